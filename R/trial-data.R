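#' Construct a multi-arm trial dataset
#'
#' Bundles per-subject covariates, the randomized arm, the scalar outcome and
#' the (known) randomization probabilities into the container consumed by all
#' learners and evaluation functions.
#'
#' @param X data frame of baseline covariates; columns may be numeric or
#'   factor (factors must carry their full level sets).
#' @param A integer vector of arm labels in `1..K`.
#' @param Y numeric outcome vector; larger values are better.
#' @param K number of arms; defaults to `max(A)`.
#' @param propensity either a single probability (uniform randomization), a
#'   length-`K` vector of arm probabilities, or an `n x K` matrix of
#'   per-subject arm probabilities.
#' @param optimal optional integer vector of true optimal arms (available for
#'   simulated data, used to score misclassification).
#'
#' @return An object of class `trial_data`: a list with elements `X`, `A`,
#'   `Y`, `K`, `n`, `p`, `propensity` (an `n x K` matrix) and optionally
#'   `optimal`.
#' @export
trial_data <- function(X, A, Y, K = max(A), propensity = 1 / K,
                       optimal = NULL) {
  X <- as.data.frame(X)
  n <- nrow(X)
  A <- as.integer(A)
  Y <- as.numeric(Y)
  stopifnot(length(A) == n, length(Y) == n)
  if (anyNA(X) || anyNA(A) || anyNA(Y))
    stop("trial_data does not allow missing values")
  if (K < 2) stop("need at least two arms")
  if (any(A < 1L | A > K)) stop("arm labels must lie in 1..K")
  if (length(unique(A)) < K)
    stop("every arm must be observed at least once")
  if (is.matrix(propensity)) {
    P <- propensity
    stopifnot(nrow(P) == n, ncol(P) == K)
  } else if (length(propensity) == 1L) {
    P <- matrix(propensity, n, K)
  } else {
    stopifnot(length(propensity) == K)
    P <- matrix(propensity, n, K, byrow = TRUE)
  }
  if (any(P <= 0))
    stop("positivity violated: every propensity must be strictly positive")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("per-subject propensities must sum to 1")
  if (!is.null(optimal)) {
    optimal <- as.integer(optimal)
    stopifnot(length(optimal) == n, all(optimal >= 1L & optimal <= K))
  }
  structure(
    list(X = X, A = A, Y = Y, K = as.integer(K), n = n, p = ncol(X),
         propensity = P, optimal = optimal),
    class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("Multi-arm trial data: n = %d subjects, p = %d covariates, K = %d arms\n",
              x$n, x$p, x$K))
  cat("Arm counts:", paste(tabulate(x$A, x$K), collapse = " / "), "\n")
  if (!is.null(x$optimal))
    cat("True optimal arms attached (simulated data)\n")
  invisible(x)
}

# Propensity of the arm each subject actually received.
observed_propensity <- function(data) {
  data$propensity[cbind(seq_len(data$n), data$A)]
}

#' Write / read a trial dataset as CSV plus a YAML sidecar
#'
#' The CSV holds covariates, arm and outcome columns; the sidecar declares
#' column types, factor levels, the arm/outcome columns, the arm propensities
#' and any recorded seed, so the dataset round-trips with types intact.
#'
#' @param data a [trial_data] object.
#' @param file path of the CSV file; the sidecar is written to
#'   `paste0(file, ".yml")`.
#' @param seed optional integer recorded in the sidecar for provenance.
#' @return `write_trial` returns `file` invisibly; `read_trial` returns a
#'   [trial_data] object.
#' @export
write_trial <- function(data, file, seed = NULL) {
  df <- cbind(data$X, .arm = data$A, .outcome = data$Y)
  utils::write.csv(df, file, row.names = FALSE)
  types <- vapply(data$X, function(col)
    if (is.factor(col)) "factor" else "numeric", character(1))
  levels <- lapply(data$X, function(col)
    if (is.factor(col)) levels(col) else NULL)
  levels <- levels[!vapply(levels, is.null, logical(1))]
  meta <- list(
    arm_column = ".arm", outcome_column = ".outcome", n_arms = data$K,
    column_types = as.list(types), factor_levels = levels,
    propensity = as.numeric(data$propensity[1, ]))
  if (!is.null(seed)) meta$seed <- seed
  yaml::write_yaml(meta, paste0(file, ".yml"), precision = 15L)
  invisible(file)
}

#' @rdname write_trial
#' @param file path of a CSV written by [write_trial].
#' @export
read_trial <- function(file) {
  meta <- yaml::read_yaml(paste0(file, ".yml"))
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  A <- df[[meta$arm_column]]
  Y <- df[[meta$outcome_column]]
  X <- df[setdiff(names(df), c(meta$arm_column, meta$outcome_column))]
  for (nm in names(meta$factor_levels))
    X[[nm]] <- factor(X[[nm]], levels = meta$factor_levels[[nm]])
  pr <- as.numeric(meta$propensity)
  trial_data(X, A, Y, K = meta$n_arms, propensity = pr / sum(pr))
}
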