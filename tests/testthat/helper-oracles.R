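# Independent oracles and small fixture builders used across test files.

# Brute-force modal controllability: explicit double loop over a separate
# eigendecomposition call, summing (1 - xi_j^2) * v_ij^2 term by term.
phi_bruteforce <- function(A) {
  e <- eigen(A)
  xi <- Re(e$values)
  V <- Re(e$vectors)
  n <- nrow(A)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      acc <- acc + (1 - xi[j]^2) * V[i, j]^2
    }
    phi[i] <- acc
  }
  phi
}

# Eigendecomposition-free oracle: since A = V diag(xi) V' with orthonormal
# V, sum_j xi_j^2 v_ij^2 = (A %*% A)[i, i], so phi = 1 - diag(A^2).
phi_matrix_square <- function(A) {
  1 - diag(A %*% A)
}

# random symmetric nonnegative weight matrix with zero diagonal
random_symmetric_counts <- function(n, seed, max_count = 30) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- rpois(sum(ut), lambda = runif(sum(ut), 0, max_count / 3)) *
    rbinom(sum(ut), 1, 0.5)
  W + t(W)
}

# closed-form GLS fixed effects for balanced twin data with an
# exchangeable within-pair covariance built from given variance components
gls_fixed_effects <- function(X, y, pair, sigma2_pair, sigma2_resid) {
  XtWX <- matrix(0, ncol(X), ncol(X))
  XtWy <- numeric(ncol(X))
  for (p in unique(pair)) {
    idx <- which(pair == p)
    S <- matrix(sigma2_pair, length(idx), length(idx))
    diag(S) <- sigma2_pair + sigma2_resid
    Si <- solve(S)
    Xp <- X[idx, , drop = FALSE]
    XtWX <- XtWX + t(Xp) %*% Si %*% Xp
    XtWy <- XtWy + t(Xp) %*% Si %*% y[idx]
  }
  as.vector(solve(XtWX, XtWy))
}

# one cross-sectional replicate: simulate a Time-1 cohort, score it through
# the full phenotype path, fit the twin-clustered model, return the
# controllability term
replicate_cross_sectional <- function(rep_seed, beta_true,
                                      n_pairs = 120, n_singletons = 20) {
  cfg <- sim_config(beta_true = beta_true, n_pairs = n_pairs,
                    n_singletons = n_singletons, timepoints = "T1",
                    seed = rep_seed)
  cohort <- simulate_cohort(cfg, keep_connectomes = FALSE)
  tab <- assemble_analysis_table(cohort$phenotype, cohort$network_means,
                                 timepoint = "T1")
  fit <- fit_lmm(tab, dv = "ef", iv = "mc_multiple_demand",
                 covariates = c("age", "race_ethnicity", "health",
                                "afqt_z"))
  model_term(fit)
}

# raw task-score table for n subjects generated from a one-factor latent
# EF, inverting the scoring conventions (used by phenotype tests)
one_factor_task_table <- function(n, seed,
                                  loadings = c(0.8, 0.7, 0.6, 0.7, 0.5, 0.6)) {
  set.seed(seed)
  latent <- rnorm(n)
  cfg <- sim_config(loadings = loadings, seed = seed)
  tab <- efcontrol:::task_scores_from_latent(latent, cfg,
                                             rngseed = seed + 13)
  list(tasks = tab, latent = latent)
}

# balanced twin analysis table with direct (connectome-free) covariates,
# for model-machinery tests where the dv is generated in closed form
direct_twin_table <- function(n_pairs, beta, icc, seed,
                              singleton_pairs = FALSE) {
  set.seed(seed)
  n <- 2 * n_pairs
  pair <- if (singleton_pairs) sprintf("P%04d", seq_len(n)) else
    rep(sprintf("P%04d", seq_len(n_pairs)), each = 2)
  pair_idx <- match(pair, unique(pair))
  x <- rnorm(n)
  u <- rnorm(length(unique(pair)))
  y <- beta * x + sqrt(icc) * u[pair_idx] + sqrt(1 - beta^2 - icc) * rnorm(n)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             twin_pair_id = pair, ef = y, mc = x,
             age = rnorm(n, 62, 2.7), race_ethnicity = rbinom(n, 1, 0.87))
}
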