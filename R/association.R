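# Twin-clustered association models: outlier exclusion, mixed models with
# a twin-pair random intercept and Satterthwaite df, BH-FDR, Spearman.

#' Flag values more than a given number of SDs from the mean
#'
#' Mean and SD are computed over all non-missing values, candidates
#' included. Used to exclude extreme network-level controllability values
#' (default: 3 SD) before modeling.
#'
#' @param values numeric vector (>= 3 non-missing).
#' @param threshold SD multiple, default 3.
#' @return logical mask, TRUE where |value - mean| > threshold * SD;
#'   missing values are never flagged.
#' @export
flag_outliers <- function(values, threshold = 3) {
  if (sum(!is.na(values)) < 3) stop("need at least 3 non-missing values")
  mu <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (s == 0) {
    warning("zero variance: no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  mask <- abs(values - mu) > threshold * s
  mask[is.na(mask)] <- FALSE
  mask
}

# Standardize the continuous columns of a model frame in place. Binary
# columns (<= 2 unique values: race, APOE, ...) are left on their 0/1
# scale, so reported coefficients are per-SD effects for continuous terms.
standardize_frame <- function(df, cols) {
  for (col in cols) {
    x <- df[[col]]
    if (is.numeric(x) && !is_binaryish(x)) df[[col]] <- zscore(x)
  }
  df
}

# Shared REML engine behind all three model-fitting fronts.
lmm_engine <- function(df, dv, rhs_terms, group, descriptor,
                       satterthwaite = TRUE) {
  fml <- stats::as.formula(paste(
    dv, "~", paste(rhs_terms, collapse = " + "),
    "+ (1 |", group, ")"
  ))
  # a cohort of singletons (every subject its own group) is a legitimate
  # degenerate case: the random intercept is then unidentified and shrinks
  # to zero, so relax lme4's group-count guards
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(fml, data = df, REML = TRUE, control = ctrl),
      error = function(e) stop("mixed model failed (", descriptor, "): ",
                               conditionMessage(e))
    ),
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
    }
  )
  conv <- fit@optinfo$conv$lme4
  # a boundary (singular) fit is an expected outcome with near-zero pair
  # variance and is reported via the `singular` flag, not a warning
  msgs <- setdiff(conv$messages,
                  grep("singular", conv$messages, value = TRUE))
  if (length(msgs) > 0) {
    grad <- tryCatch(max(abs(fit@optinfo$derivs$gradient)), error = function(e) NA)
    warning("convergence diagnostics (", descriptor, "): ",
            paste(msgs, collapse = "; "),
            "; max |gradient| = ", format(grad))
  }
  co <- tryCatch(summary(fit, ddf = "Satterthwaite")$coefficients,
                 error = function(e) NULL)
  p_rank <- length(lme4::fixef(fit))
  n_obs <- stats::nobs(fit)
  fallback_df <- n_obs - p_rank
  df_method <- "satterthwaite"
  if (is.null(co) || any(!is.finite(co[, "df"])) || !satterthwaite) {
    warning("Satterthwaite df unavailable; using residual df (",
            fallback_df, ")")
    co0 <- summary(fit)$coefficients
    co <- cbind(co0[, 1:2, drop = FALSE], df = fallback_df,
                `t value` = co0[, 1] / co0[, 2], `Pr(>|t|)` = NA)
    co[, "Pr(>|t|)"] <- 2 * stats::pt(-abs(co[, "t value"]), df = fallback_df)
    df_method <- "residual"
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_pair <- vc$vcov[vc$grp == group][1]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"][1]
  tcrit <- stats::qt(0.975, df = co[, "df"])
  terms_df <- data.frame(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    t = co[, "t value"],
    df = co[, "df"],
    p = co[, "Pr(>|t|)"],
    ci_lo = co[, "Estimate"] - tcrit * co[, "Std. Error"],
    ci_hi = co[, "Estimate"] + tcrit * co[, "Std. Error"],
    row.names = NULL
  )
  structure(
    list(
      terms = terms_df,
      sigma2_pair = sigma2_pair,
      sigma2_resid = sigma2_resid,
      n_obs = n_obs,
      n_pairs = length(unique(df[[group]])),
      singular = lme4::isSingular(fit),
      df_method = df_method,
      descriptor = descriptor,
      dv = dv, iv = rhs_terms[1]
    ),
    class = "ef_model"
  )
}

#' @exportS3Method base::print
print.ef_model <- function(x, ...) {
  cat(x$descriptor, "\n")
  cat(sprintf("  n = %d subjects in %d twin groups; sigma2_pair = %.4f, sigma2_resid = %.4f%s\n",
              x$n_obs, x$n_pairs, x$sigma2_pair, x$sigma2_resid,
              if (x$singular) " (singular fit)" else ""))
  print(cbind(x$terms[1], round(x$terms[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.ef_model <- function(x, ...) x$terms

#' Term row for the focal predictor of a fitted model
#' @param model an `ef_model`.
#' @param term term name; default the model's independent variable.
#' @return one-row data.frame (estimate, se, t, df, p, ci_lo, ci_hi).
#' @export
model_term <- function(model, term = model$iv) {
  row <- model$terms[model$terms$term == term, ]
  if (nrow(row) != 1) stop("term '", term, "' not found in model")
  row
}

#' Twin-clustered linear mixed model with standardized coefficients
#'
#' Fits `dv ~ iv + covariates + (1 | group)` by REML with a random
#' intercept per twin pair, after z-scoring the dependent variable, the
#' independent variable, and continuous covariates within the analyzed
#' (listwise-complete) rows — so reported estimates are standardized
#' effects per SD. Binary covariates stay on their 0/1 coding. Inference
#' uses the Satterthwaite degrees-of-freedom approximation, falling back
#' to residual df with a warning when unavailable.
#'
#' @param data data.frame with one row per subject (or subject-timepoint).
#' @param dv,iv dependent and independent variable column names.
#' @param covariates character vector of covariate columns.
#' @param group twin-pair id column (default `"twin_pair_id"`).
#' @param standardize z-score continuous variables first (default TRUE).
#' @param min_n minimum rows after listwise deletion (default 20).
#' @return an `ef_model` object: `terms` data.frame (term, estimate, se,
#'   t, df, p, ci_lo, ci_hi), variance components `sigma2_pair` and
#'   `sigma2_resid`, `n_obs`, `n_pairs`, convergence flags.
#' @export
fit_lmm <- function(data, dv, iv, covariates = character(),
                    group = "twin_pair_id", standardize = TRUE,
                    min_n = 20) {
  used <- c(dv, iv, covariates, group)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  df <- data[stats::complete.cases(data[, used, drop = FALSE]),
             used, drop = FALSE]
  if (nrow(df) < min_n) {
    stop("too few rows after listwise deletion (", nrow(df),
         " < ", min_n, ")")
  }
  for (col in c(dv, iv)) {
    if (stats::sd(as.numeric(df[[col]])) == 0) stop("constant column: ", col)
  }
  if (standardize) df <- standardize_frame(df, c(dv, iv, covariates))
  lmm_engine(df, dv, c(iv, covariates), group,
             descriptor = paste0(dv, " ~ ", iv,
                                 if (length(covariates) > 0)
                                   paste0(" + ", paste(covariates, collapse = " + "))
                                 else "",
                                 " + (1 | ", group, ")"))
}

#' Per-subject longitudinal difference table (Time 1 minus Time 2)
#'
#' Collapses a two-timepoint analysis table to one row per subject with
#' difference columns `d_ef`, `d_mc_*`, `d_age`, `d_health` computed as
#' Time 1 minus Time 2, keeping time-invariant covariates
#' (race/ethnicity, young-adult cognitive ability, APOE, twin pair) from
#' the Time 1 row. Subjects missing either timepoint are dropped.
#'
#' @param table long analysis table with a `timepoint` column ("T1"/"T2").
#' @return one-row-per-subject data.frame of differences.
#' @export
make_change_table <- function(table) {
  t1 <- table[table$timepoint == "T1", , drop = FALSE]
  t2 <- table[table$timepoint == "T2", , drop = FALSE]
  common <- intersect(t1$subject_id, t2$subject_id)
  if (length(common) == 0) stop("no subjects present at both timepoints")
  t1 <- t1[match(common, t1$subject_id), ]
  t2 <- t2[match(common, t2$subject_id), ]
  diff_cols <- intersect(c("ef", "mc_control", "mc_multiple_demand",
                           "age", "health"), names(table))
  out <- data.frame(subject_id = common)
  for (col in diff_cols) {
    out[[paste0("d_", col)]] <- t1[[col]] - t2[[col]]
  }
  for (col in intersect(c("race_ethnicity", "afqt_z", "apoe_e4",
                          "twin_pair_id"), names(table))) {
    out[[col]] <- t1[[col]]
  }
  out
}

#' Longitudinal change model for one network
#'
#' Fits the difference in executive function (Time 1 minus Time 2) on the
#' difference in that network's mean modal controllability, with
#' differences in age and health plus race/ethnicity and young-adult
#' cognitive ability as covariates, and the twin-pair random intercept
#' retained (pairs stay correlated even after differencing).
#'
#' @param table a [make_change_table()] result (or equivalent).
#' @param network `"control"` or `"multiple_demand"`.
#' @param covariates covariate columns, default
#'   `c("d_age", "d_health", "race_ethnicity", "afqt_z")`.
#' @inheritParams fit_lmm
#' @return an `ef_model`.
#' @export
fit_longitudinal_change <- function(table, network = c("multiple_demand", "control"),
                                    covariates = c("d_age", "d_health",
                                                   "race_ethnicity", "afqt_z"),
                                    group = "twin_pair_id", min_n = 20) {
  network <- match.arg(network)
  iv <- paste0("d_mc_", network)
  if (!iv %in% names(table)) stop("column not found: ", iv)
  for (col in c("d_ef", iv)) {
    x <- table[[col]]
    if (all(x[!is.na(x)] == 0)) {
      stop("degenerate differences: ", col, " is identically zero")
    }
  }
  fit_lmm(table, dv = "d_ef", iv = iv, covariates = covariates,
          group = group, min_n = min_n)
}

#' Moderation (interaction) model
#'
#' Adds a moderator and its product with the network-controllability term
#' to the cross-sectional model. The product is formed from the
#' standardized components (continuous variables z-scored, binary
#' moderators kept 0/1) and entered as an explicit `interaction` column,
#' so the reported interaction estimate is on the product-of-standardized
#' scale.
#'
#' @param table analysis table (one timepoint).
#' @param iv controllability column, e.g. `"mc_multiple_demand"`.
#' @param moderator moderator column (`"apoe_e4"` or `"afqt_z"`).
#' @param dv dependent column, default `"ef"`.
#' @param covariates additional covariates (the moderator is removed from
#'   this list automatically if present).
#' @inheritParams fit_lmm
#' @return an `ef_model`; the interaction row is named `"interaction"`.
#' @export
fit_moderation <- function(table, iv, moderator, dv = "ef",
                           covariates = c("age", "race_ethnicity",
                                          "health", "afqt_z"),
                           group = "twin_pair_id", min_n = 20) {
  covariates <- setdiff(covariates, moderator)
  used <- c(dv, iv, moderator, covariates, group)
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "))
  }
  df <- table[stats::complete.cases(table[, used, drop = FALSE]),
              used, drop = FALSE]
  if (nrow(df) < min_n) {
    stop("too few rows after listwise deletion (", nrow(df), ")")
  }
  modx <- as.numeric(df[[moderator]])
  if (stats::sd(modx) == 0) stop("constant moderator: ", moderator)
  df <- standardize_frame(df, c(dv, iv, moderator, covariates))
  df$interaction <- as.numeric(df[[iv]]) * as.numeric(df[[moderator]])
  lmm_engine(df, dv, c(iv, moderator, "interaction", covariates), group,
             descriptor = paste0(dv, " ~ ", iv, " * ", moderator,
                                 " + covariates + (1 | ", group, ")"))
}

#' Benjamini-Hochberg FDR adjustment over a declared test family
#'
#' Step-up adjusted p-values: with the m raw p-values sorted ascending,
#' the k-th adjusted value is min over j >= k of (m/j) p_(j), capped at 1,
#' returned in input order.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; p from t = rho * sqrt((n-2)/(1-rho^2)) on
#' n - 2 df. Pairs with any missing value are dropped.
#'
#' @param x,y numeric vectors.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  spearman_stat(x, y)
}
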