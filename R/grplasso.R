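# Group lasso by block coordinate descent.
#
# Objective: (1/2n) ||y - b0 - X beta||^2 + lambda * sum_g w_g ||beta_g||_2
# with w_g = sqrt(group size) for penalized groups. The intercept is the
# only unpenalized term and is absorbed by centering. Each group's columns
# are orthonormalized (SVD) before descent, which makes the block update an
# exact groupwise soft-threshold; coefficients are mapped back to the input
# column scale afterwards. Degenerate (zero-variance) directions within a
# group are dropped; a fully degenerate group is dropped with a warning.

grp_prepare <- function(M, y, group) {
  n <- nrow(M)
  keep_cols <- which(apply(M, 2, function(c) stats::sd(c) > 0))
  groups <- sort(unique(group[keep_cols]))
  xbar <- colMeans(M)
  ybar <- mean(y)
  yc <- y - ybar
  blocks <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    idx <- intersect(which(group == g), keep_cols)
    Xg <- sweep(M[, idx, drop = FALSE], 2, xbar[idx])
    sv <- svd(Xg)
    ok <- sv$d > max(sv$d[1], 1e-8) * 1e-8
    if (!any(ok)) next
    Z <- sv$u[, ok, drop = FALSE] * sqrt(n)           # Z'Z = n I
    Tg <- sv$v[, ok, drop = FALSE] %*%
      diag(1 / sv$d[ok], sum(ok)) * sqrt(n)           # beta_orig = Tg beta_z
    blocks[[gi]] <- list(g = g, idx = idx, Z = Z, T = Tg, r = sum(ok))
  }
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) < length(groups))
    warning("dropped degenerate group(s) from the design")
  list(blocks = blocks, yc = yc, ybar = ybar, xbar = xbar, n = n)
}

# Solve the path for a fixed lambda sequence with warm starts.
# pen_weight: named by group id, penalty weight per group (sqrt group size).
grp_path_core <- function(prep, pen_weight, lambda, tol = 1e-7,
                          maxit = 5000L) {
  blocks <- prep$blocks
  n <- prep$n
  yc <- prep$yc
  B <- lapply(blocks, function(b) numeric(b$r))
  r <- yc
  L <- length(lambda)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    lam <- lambda[l]
    obj_old <- Inf
    for (it in seq_len(maxit)) {
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        s <- B[[bi]] + drop(crossprod(b$Z, r)) / n
        ns <- sqrt(sum(s^2))
        thr <- lam * pen_weight[as.character(b$g)]
        newb <- if (ns <= thr) numeric(b$r) else (1 - thr / ns) * s
        d <- newb - B[[bi]]
        if (any(d != 0)) {
          r <- r - drop(b$Z %*% d)
          B[[bi]] <- newb
        }
      }
      obj <- sum(r^2) / (2 * n) + lam *
        sum(vapply(seq_along(blocks), function(bi)
          pen_weight[as.character(blocks[[bi]]$g)] *
            sqrt(sum(B[[bi]]^2)), numeric(1)))
      if (is.finite(obj_old) &&
          abs(obj_old - obj) <= tol * max(1, abs(obj_old))) break
      obj_old <- obj
    }
    out[[l]] <- lapply(B, identity)
  }
  list(coefs = out, blocks = blocks)
}

# Full fit: returns coefficients on input columns (ncol(M) x L), intercepts,
# lambda grid and per-group selection.
grplasso_path <- function(M, y, group, penalized, lambda = NULL,
                          nlambda = 50L, lambda_min_ratio = 1e-4,
                          tol = 1e-7, maxit = 5000L) {
  prep <- grp_prepare(M, y, group)
  gids <- vapply(prep$blocks, function(b) b$g, numeric(1))
  sizes <- vapply(prep$blocks, function(b) length(b$idx), numeric(1))
  pw <- ifelse(penalized[gids], sqrt(sizes), 0)
  names(pw) <- as.character(gids)
  if (is.null(lambda)) {
    lmax <- max(vapply(seq_along(prep$blocks), function(bi) {
      if (pw[bi] == 0) return(0)
      sqrt(sum((crossprod(prep$blocks[[bi]]$Z, prep$yc) / prep$n)^2)) / pw[bi]
    }, numeric(1)))
    if (lmax <= 0) lmax <- 1
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  fit <- grp_path_core(prep, pw, lambda, tol, maxit)
  P <- ncol(M)
  L <- length(lambda)
  beta <- matrix(0, P, L, dimnames = list(colnames(M), NULL))
  for (l in seq_len(L))
    for (bi in seq_along(fit$blocks)) {
      b <- fit$blocks[[bi]]
      beta[b$idx, l] <- b$T %*% fit$coefs[[l]][[bi]]
    }
  b0 <- prep$ybar - drop(crossprod(beta, prep$xbar))
  selected <- matrix(FALSE, max(group), L)
  for (l in seq_len(L))
    for (bi in seq_along(fit$blocks)) {
      b <- fit$blocks[[bi]]
      selected[b$g, l] <- sqrt(sum(fit$coefs[[l]][[bi]]^2)) > 0
    }
  list(lambda = lambda, beta = beta, b0 = b0, selected = selected)
}

# 5-fold CV over the lambda path; minimum-MSE rule.
cv_grplasso <- function(M, y, group, penalized, nfolds = 5L, lambda = NULL,
                        nlambda = 50L, lambda_min_ratio = 1e-4, ...) {
  full <- grplasso_path(M, y, group, penalized, lambda = lambda,
                        nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio, ...)
  n <- nrow(M)
  fold <- sample(rep_len(seq_len(nfolds), n))
  L <- length(full$lambda)
  err <- matrix(NA_real_, nfolds, L)
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    pf <- grplasso_path(M[tr, , drop = FALSE], y[tr], group, penalized,
                        lambda = full$lambda, ...)
    pred <- M[!tr, , drop = FALSE] %*% pf$beta
    pred <- sweep(pred, 2, pf$b0, "+")
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  best <- which.min(cvm)
  list(lambda = full$lambda, cvm = cvm, best = best,
       lambda_min = full$lambda[best],
       beta = full$beta[, best], b0 = full$b0[best],
       selected = full$selected[, best], path = full)
}
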