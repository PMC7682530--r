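# Shared covariate encoder and grouped interaction design.
#
# The regression basis is (1, X, A, XA): intercept, covariate main effects
# (factors dummy-coded at the factor level), K-1 arm dummies (arm 1 is the
# reference), and one arm-by-covariate interaction block per covariate.
# Groups: each categorical covariate's dummies form one group, the arm
# dummies one group, each interaction block one group; the hierarchy map
# links every interaction group to its two parents (the covariate's main
# group and the arm group).

# Covariate encoder captured from training data.
make_encoder <- function(X) {
  X <- as.data.frame(X)
  cols <- lapply(X, function(col) {
    if (is.factor(col)) list(type = "factor", levels = levels(col))
    else if (is.character(col)) list(type = "factor", levels = sort(unique(col)))
    else list(type = "numeric")
  })
  list(names = names(X), cols = cols)
}

# Main-effect columns of one covariate as a matrix (drops the first level of
# factors). Errors on levels unseen at training time.
encode_covariate <- function(enc_col, x, name) {
  if (enc_col$type == "numeric") {
    m <- matrix(as.numeric(x), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), enc_col$levels)
  if (length(bad))
    stop(sprintf("unseen level(s) %s in column '%s'",
                 paste(bad, collapse = ", "), name))
  lv <- enc_col$levels
  m <- vapply(lv[-1], function(l) as.numeric(x == l), numeric(length(x)))
  m <- matrix(m, ncol = length(lv) - 1L)
  colnames(m) <- paste0(name, lv[-1])
  m
}

#' Grouped interaction design for penalized least squares
#'
#' Builds the basis `(1, X, A, XA)` together with its group structure:
#' intercept, one main-effect group per covariate, one group of `K - 1` arm
#' dummies, and one arm-by-covariate interaction group per covariate, with a
#' hierarchy map linking each interaction group to its two parent groups.
#'
#' @param X covariate data frame.
#' @param A integer arm vector in `1..K` (may be omitted when only the
#'   encoder is needed).
#' @param K number of arms.
#' @return An object of class `grouped_design`: list with the design
#'   `matrix`, per-column `group` index, `group_info` (type, covariate,
#'   penalized flag), the `hierarchy` map, the covariate `encoder` and `K`.
#' @export
build_design <- function(X, A, K = 3L) {
  if (K < 2) stop("need K >= 2 arms")
  enc <- make_encoder(X)
  d <- design_matrix(enc, X, A, K)
  structure(list(matrix = d$M, group = d$group, group_info = d$group_info,
                 hierarchy = d$hierarchy, encoder = enc, K = as.integer(K)),
            class = "grouped_design")
}

# Basis matrix plus grouping for given covariates and arms.
design_matrix <- function(enc, X, A, K) {
  X <- as.data.frame(X)
  n <- nrow(X)
  A <- as.integer(A)
  stopifnot(length(A) == n)
  mains <- lapply(seq_along(enc$names), function(j)
    encode_covariate(enc$cols[[j]], X[[enc$names[j]]], enc$names[j]))
  arm <- vapply(2:K, function(a) as.numeric(A == a), numeric(n))
  arm <- matrix(arm, ncol = K - 1L)
  colnames(arm) <- paste0("arm", 2:K)

  blocks <- list(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  group_info <- list(list(type = "intercept", cov = NA, penalized = FALSE))
  for (j in seq_along(mains)) {
    blocks[[length(blocks) + 1L]] <- mains[[j]]
    group_info[[length(group_info) + 1L]] <-
      list(type = "main", cov = enc$names[j], penalized = TRUE)
  }
  blocks[[length(blocks) + 1L]] <- arm
  group_info[[length(group_info) + 1L]] <-
    list(type = "arm", cov = NA, penalized = TRUE)
  arm_gid <- length(group_info)
  hierarchy <- list()
  for (j in seq_along(mains)) {
    Mj <- mains[[j]]
    inter <- do.call(cbind, lapply(seq_len(ncol(arm)), function(k) {
      m <- Mj * arm[, k]
      colnames(m) <- paste0(colnames(Mj), ":", colnames(arm)[k])
      m
    }))
    blocks[[length(blocks) + 1L]] <- inter
    group_info[[length(group_info) + 1L]] <-
      list(type = "inter", cov = enc$names[j], penalized = TRUE)
    hierarchy[[length(hierarchy) + 1L]] <-
      list(inter = length(group_info), main = j + 1L, arm = arm_gid)
  }
  M <- do.call(cbind, blocks)
  group <- rep(seq_along(blocks), vapply(blocks, ncol, integer(1)))
  list(M = M, group = group, group_info = group_info, hierarchy = hierarchy)
}

# Expanded (overlapped) design realizing the strong-hierarchy penalty: each
# interaction group is augmented with copies of its parent main-effect and
# arm columns, turning the overlapped group lasso into an ordinary one.
# orig maps expanded columns back to basis columns (coefficients are summed
# over copies).
expand_hierarchy <- function(design) {
  M <- design$matrix
  group <- design$group
  info <- design$group_info
  keep <- which(vapply(info, function(g) g$type != "inter", logical(1)))
  cols <- which(group %in% keep)
  newM <- list(M[, cols, drop = FALSE])
  orig <- list(cols)
  newgroup <- list(match(group[cols], keep))
  ginfo <- info[keep]
  gid <- length(keep)
  for (h in design$hierarchy) {
    mc <- which(group == h$main)
    ac <- which(group == h$arm)
    ic <- which(group == h$inter)
    idx <- c(mc, ac, ic)
    gid <- gid + 1L
    newM[[length(newM) + 1L]] <- M[, idx, drop = FALSE]
    orig[[length(orig) + 1L]] <- idx
    newgroup[[length(newgroup) + 1L]] <- rep(gid, length(idx))
    ginfo[[gid]] <- list(type = "inter", cov = info[[h$inter]]$cov,
                         penalized = TRUE)
  }
  list(M = do.call(cbind, newM), group = unlist(newgroup),
       group_info = ginfo, orig = unlist(orig), n_basis = ncol(M))
}
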