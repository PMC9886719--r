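# Executive-function phenotype scoring: residualized task indicators, the
# common EF factor score, and covariate transforms.

#' OLS residualization of a task score on elementary components
#'
#' Replaces a score by its ordinary-least-squares residual on an intercept
#' plus one or more adjuster vectors, removing variance accounted for by
#' more elementary task components so the executive component is isolated.
#' Residuals are computed on complete cases and returned in input order
#' with NA where any input was missing; they are exactly orthogonal to the
#' intercept and to every adjuster.
#'
#' @param target numeric vector.
#' @param adjusters numeric vector, matrix, data.frame, or NULL
#'   (intercept-only: residuals are the centered target).
#' @return numeric vector of residuals, same length as `target`.
#' @export
residualize <- function(target, adjusters = NULL) {
  n <- length(target)
  if (is.null(adjusters)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(as.data.frame(adjusters))
    if (nrow(X) != n) stop("target and adjusters must have equal length")
  }
  cc <- stats::complete.cases(target, X)
  if (sum(cc) == 0) stop("all-missing target")
  if (sum(cc) < ncol(X) + 2) {
    stop("need at least 2 more observations than adjusters")
  }
  D <- cbind(`(Intercept)` = 1, X)[cc, , drop = FALSE]
  if (qr(D)$rank < ncol(D)) stop("rank-deficient adjuster set")
  fit <- stats::lm.fit(D, target[cc])
  out <- rep(NA_real_, n)
  out[cc] <- fit$residuals
  out
}

# the ten raw task columns the indicator builder consumes
task_columns <- c(
  "stroop_colorword", "stroop_word", "stroop_color",
  "trails_switch_time", "trails_single_time",
  "catswitch_correct_switches", "catfluency_correct",
  "letter_number_total", "reading_span_total", "digit_span_total"
)

ef_indicator_names <- c(
  "stroop", "trails", "catswitch", "letter_number", "reading_span",
  "digit_span"
)

#' Build the six oriented, z-scored executive-function indicators
#'
#' From raw neuropsychological task scores:
#' \itemize{
#'   \item stroop: color-word correct residualized on word and color
#'     conditions;
#'   \item trails: switching time residualized on single-task time, then
#'     negated (lower time = better);
#'   \item catswitch: correct switches residualized on category-fluency
#'     correct responses;
#'   \item letter_number, reading_span, digit_span: totals used directly.
#' }
#' Each indicator is z-scored over its non-missing scoring sample, so
#' higher always means better executive function.
#'
#' @param tasks data.frame with the ten raw task columns (see
#'   `efcontrol:::task_columns`); extra columns (ids, covariates) pass
#'   through untouched in the attribute `"ids"`.
#' @return data.frame of six indicator columns (class `ef_indicators`),
#'   rows aligned with `tasks`.
#' @export
build_indicators <- function(tasks) {
  missing_cols <- setdiff(task_columns, names(tasks))
  if (length(missing_cols) > 0) {
    stop("missing task columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tasks) < 10) stop("scoring sample too small (need >= 10 rows)")
  raw <- list(
    stroop = residualize(tasks$stroop_colorword,
                         tasks[, c("stroop_word", "stroop_color")]),
    trails = -residualize(tasks$trails_switch_time,
                          tasks$trails_single_time),
    catswitch = residualize(tasks$catswitch_correct_switches,
                            tasks$catfluency_correct),
    letter_number = tasks$letter_number_total,
    reading_span = tasks$reading_span_total,
    digit_span = tasks$digit_span_total
  )
  out <- as.data.frame(lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("zero variance indicator: ", nm)
    (x - mean(x, na.rm = TRUE)) / s
  }))
  names(out) <- ef_indicator_names
  class(out) <- c("ef_indicators", "data.frame")
  out
}

#' Common executive-function factor score
#'
#' Scores a single common factor from the six EF indicators. By default a
#' one-factor maximum-likelihood model is estimated on the complete-case
#' scoring sample ([stats::factanal]); alternatively, fixed loadings may be
#' supplied (uniquenesses taken as 1 - loading^2 on the standardized
#' metric) and the estimation step is skipped. Scores are
#' regression-method (Thomson) scores, z-scored over the scored sample.
#' Loading signs follow the majority-positive convention so higher scores
#' indicate better executive function.
#'
#' A subject's score is missing if any indicator is missing unless
#' `allow_partial = TRUE`, in which case Thomson weights are recomputed
#' from the model-implied covariance of the observed subset.
#'
#' @param indicators a [build_indicators()] result (or any data.frame of
#'   six numeric indicator columns).
#' @param loadings optional fixed numeric 6-vector.
#' @param allow_partial score subjects with partially missing indicators.
#' @return list of class `ef_factor_score`: `scores` (z-metric, aligned
#'   with rows), `loadings`, `uniquenesses`, `method`.
#' @export
ef_factor_score <- function(indicators, loadings = NULL,
                            allow_partial = FALSE) {
  X <- as.matrix(as.data.frame(indicators)[,
    intersect(ef_indicator_names, names(indicators))])
  if (ncol(X) == 0) X <- as.matrix(as.data.frame(indicators))
  k <- ncol(X)
  if (k < 6) stop("need six indicators, got ", k)
  cc <- stats::complete.cases(X)
  if (sum(cc) < k + 2) stop("too few complete rows to score the factor")
  Z <- scale(X[cc, , drop = FALSE])
  method <- "ml_regression"
  if (is.null(loadings)) {
    R <- stats::cor(Z)
    if (min(1 - abs(R[upper.tri(R)])) < 1e-10) {
      # degenerate one-factor case: indicators are copies of one vector
      loadings <- rep(1, k)
      uniq <- rep(0, k)
      scores_cc <- zscore(Z[, 1])
      method <- "degenerate"
    } else {
      fit <- tryCatch(
        stats::factanal(covmat = R, factors = 1, n.obs = sum(cc)),
        error = function(e) stop("factor model did not converge: ",
                                 conditionMessage(e))
      )
      loadings <- as.vector(fit$loadings)
      uniq <- fit$uniquenesses
      if (any(uniq <= 0.006)) {
        stop("Heywood case: uniqueness at bound for indicator(s) ",
             paste(colnames(X)[uniq <= 0.006], collapse = ", "),
             " (loadings: ", paste(round(loadings, 3), collapse = ", "), ")")
      }
    }
  } else {
    if (length(loadings) != k) stop("fixed loadings must have length ", k)
    if (any(abs(loadings) >= 1)) {
      stop("fixed loadings must lie in (-1, 1) on the standardized metric")
    }
    uniq <- 1 - loadings^2
    method <- "fixed_loadings"
  }
  if (sum(loadings > 0) < sum(loadings < 0)) loadings <- -loadings
  if (method != "degenerate") {
    Sigma <- tcrossprod(loadings) + diag(uniq)
    w <- solve(Sigma, loadings) # Thomson regression weights
    scores_cc <- zscore(as.vector(Z %*% w))
  }
  scores <- rep(NA_real_, nrow(X))
  scores[cc] <- scores_cc
  if (allow_partial && any(!cc) && method != "degenerate") {
    mu <- attr(Z, "scaled:center")
    sdv <- attr(Z, "scaled:scale")
    Sigma <- tcrossprod(loadings) + diag(uniq)
    for (i in which(!cc)) {
      obs <- which(!is.na(X[i, ]))
      if (length(obs) == 0) next
      zi <- (X[i, obs] - mu[obs]) / sdv[obs]
      wi <- solve(Sigma[obs, obs, drop = FALSE], loadings[obs])
      scores[i] <- sum(zi * wi)
    }
    # re-standardize jointly so the z-metric still holds
    scores <- (scores - mean(scores, na.rm = TRUE)) /
      stats::sd(scores, na.rm = TRUE)
  }
  structure(
    list(scores = scores, loadings = loadings, uniquenesses = uniq,
         method = method),
    class = "ef_factor_score"
  )
}

#' Probit transform of a percentile score
#'
#' Inverse standard-normal CDF of percentile/100. Used for young-adult
#' general cognitive ability (AFQT) percentiles. Values outside (0, 100)
#' are an error — no clamping.
#'
#' @param pctile numeric vector of percentiles, each strictly in (0, 100).
#' @return probit (z) values.
#' @export
probit_percentile <- function(pctile) {
  bad <- !is.na(pctile) & (pctile <= 0 | pctile >= 100)
  if (any(bad)) {
    stop("percentile outside (0, 100): ",
         paste(utils::head(pctile[bad], 3), collapse = ", "))
  }
  stats::qnorm(pctile / 100)
}

#' Probit-transform and z-score percentiles over the sample
#' @param pctile percentiles in (0, 100); NA allowed.
#' @return z-scored probit values.
#' @export
probit_z <- function(pctile) {
  zscore(probit_percentile(pctile))
}

#' Cap a comorbidity health index at 3
#'
#' Health status is a chronic-condition count (higher = poorer health);
#' scores above 3 are recoded to 3 to improve the distribution.
#'
#' @param score nonnegative integer vector (NA allowed).
#' @return integer vector with values in 0..3.
#' @export
cap_health <- function(score) {
  ok <- is.na(score) | (score >= 0 & score == round(score))
  if (!all(ok)) stop("health score must be a nonnegative integer")
  as.integer(pmin(score, 3L))
}

#' Practice-effect adjustment hook
#'
#' Returning participants' task scores are expected to be adjusted for
#' practice effects upstream; no adjustment formula is implemented here.
#' This hook passes through externally pre-adjusted scores when supplied
#' and otherwise returns the input unchanged.
#'
#' @param scores raw task-score data.frame.
#' @param adjusted optional externally practice-adjusted replacement.
#' @return `adjusted` if given, else `scores`.
#' @export
adjust_practice <- function(scores, adjusted = NULL) {
  if (is.null(adjusted)) return(scores)
  if (!identical(dim(adjusted), dim(scores))) {
    stop("adjusted scores must match the raw score table's dimensions")
  }
  adjusted
}
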