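# Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed and integer ids
#'
#' Counter-based scheme: the base seed and each id are folded into a
#' linear-congruential accumulator modulo 2^31 - 1, so child streams for
#' (subject, timepoint, stage) triples are deterministic functions of the
#' base seed and independent of global RNG state.
#'
#' @param seed base integer seed.
#' @param ... further integer counters (subject index, stream index, ...).
#' @return a positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  stopifnot(length(ids) >= 1, all(is.finite(ids)))
  m <- 2147483647
  h <- 0
  for (x in as.numeric(ids)) {
    h <- (h * 48271 + abs(x) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# z-score a numeric vector over its non-missing entries
zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop("zero variance: cannot z-score a constant vector")
  }
  (x - mu) / s
}

# Spearman rank correlation with average ranks for ties and the
# t-approximation p-value on n - 2 degrees of freedom.
spearman_stat <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired non-missing values")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance in one of the inputs")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# is a column effectively binary (<= 2 unique non-missing values)?
is_binaryish <- function(x) {
  length(unique(x[!is.na(x)])) <= 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
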