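# Synthetic study-condition generator: streamline-count connectomes with
# heterogeneous node strengths, two timepoints with tunable edge stability,
# and twin-structured cohorts whose executive-function phenotype is driven
# by network modal controllability with known ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 260 subjects (120 twin pairs +
#' 20 singletons, matching the larger cross-sectional wave), APOE-e4
#' prevalence 0.24, age ~ N(61.75, 2.7) with a 5.7-year follow-up,
#' young-adult cognitive ability percentiles with mean ~62 and SD ~21,
#' a capped-Poisson comorbidity index that worsens slightly at Time 2,
#' a standardized controllability-to-EF effect beta_true = 0.12, a
#' longitudinal change coupling of 0.3, and edge-level timepoint
#' stability 0.95 (the high-stability regime in which group topography is
#' nearly preserved across waves). The connectome edge model draws
#' log-normal node-strength propensities shared across the cohort
#' (subject-jittered), Bernoulli edge presence at the target density, and
#' Poisson streamline counts scaled by the endpoint propensities.
#'
#' @param n_nodes parcels per connectome (100 default; 400 mimics the
#'   full cortical atlas).
#' @param density expected edge density in (0, 1].
#' @param base_count mean streamline count of a present edge.
#' @param strength_sdlog SD (log scale) of the cohort-level node
#'   propensity profile — controls strength heterogeneity.
#' @param subject_sdlog SD (log scale) of per-subject propensity jitter.
#' @param n_pairs,n_singletons twin pairs and unpaired subjects.
#' @param pair_icc intraclass correlation of EF within twin pair.
#' @param beta_true standardized controllability -> EF effect.
#' @param delta_coupling standardized coupling of controllability change
#'   to EF change (Time 1 minus Time 2 metric).
#' @param decline_sd between-person SD of the latent EF decline.
#' @param mean_decline mean latent EF decline from T1 to T2 (z units).
#' @param loadings 6-vector of EF indicator loadings.
#' @param gamma_health,gamma_afqt standardized covariate effects on EF.
#' @param interaction_apoe,interaction_afqt moderation effect sizes
#'   (products with standardized controllability), 0 = no moderation.
#' @param apoe_prevalence,white_prevalence Bernoulli rates.
#' @param age_mean,age_sd,follow_up_years age structure (years).
#' @param afqt_mean_z,afqt_sd_z latent normal generating AFQT percentiles
#'   via 100 * pnorm(latent).
#' @param health_rate Poisson rate of the raw comorbidity count (capped
#'   at 6); `health_worsen_prob` chance of gaining one condition by T2.
#' @param health_worsen_prob see above.
#' @param timepoint_stability edge-level mixing weight of T1 into T2 in
#'   [0, 1]; 1 means T2 = T1 exactly.
#' @param timepoints `"both"` or `"T1"` (cross-sectional-only cohorts are
#'   cheaper to generate).
#' @param driver_network network whose mean controllability drives EF.
#' @param seed base integer seed; all randomness derives from it through
#'   counter-based child seeds.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 100, density = 0.3, base_count = 20,
                       strength_sdlog = 0.6, subject_sdlog = 0.2,
                       n_pairs = 120, n_singletons = 20,
                       pair_icc = 0.3, beta_true = 0.12,
                       delta_coupling = 0.3, decline_sd = 0.5,
                       mean_decline = 0.3,
                       loadings = c(0.8, 0.7, 0.6, 0.7, 0.5, 0.6),
                       gamma_health = -0.2, gamma_afqt = 0.4,
                       interaction_apoe = 0, interaction_afqt = 0,
                       apoe_prevalence = 0.24, white_prevalence = 0.87,
                       age_mean = 61.75, age_sd = 2.7,
                       follow_up_years = 5.7,
                       afqt_mean_z = 0.36, afqt_sd_z = 0.65,
                       health_rate = 1.0, health_worsen_prob = 0.3,
                       timepoint_stability = 0.95,
                       timepoints = c("both", "T1"),
                       driver_network = "multiple_demand", seed = 1) {
  cfg <- list(
    n_nodes = n_nodes, density = density, base_count = base_count,
    strength_sdlog = strength_sdlog, subject_sdlog = subject_sdlog,
    n_pairs = n_pairs, n_singletons = n_singletons, pair_icc = pair_icc,
    beta_true = beta_true, delta_coupling = delta_coupling,
    decline_sd = decline_sd, mean_decline = mean_decline,
    loadings = loadings, gamma_health = gamma_health,
    gamma_afqt = gamma_afqt, interaction_apoe = interaction_apoe,
    interaction_afqt = interaction_afqt,
    apoe_prevalence = apoe_prevalence, white_prevalence = white_prevalence,
    age_mean = age_mean, age_sd = age_sd,
    follow_up_years = follow_up_years, afqt_mean_z = afqt_mean_z,
    afqt_sd_z = afqt_sd_z, health_rate = health_rate,
    health_worsen_prob = health_worsen_prob,
    timepoint_stability = timepoint_stability,
    timepoints = match.arg(timepoints),
    driver_network = driver_network, seed = as.integer(seed)
  )
  probs <- c(density, apoe_prevalence, white_prevalence,
             health_worsen_prob, timepoint_stability)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_nodes < 5) stop("need at least 5 nodes")
  if (n_pairs + n_singletons < 1) stop("empty cohort")
  if (length(loadings) != 6 || any(abs(loadings) >= 1)) {
    stop("loadings must be 6 values in (-1, 1)")
  }
  if (abs(beta_true) >= 1) stop("|beta_true| must be < 1")
  if (any(c(strength_sdlog, subject_sdlog, decline_sd, age_sd,
            afqt_sd_z) <= 0)) {
    stop("scale parameters must be positive")
  }
  resid_var <- 1 - beta_true^2 - gamma_health^2 - gamma_afqt^2 -
    pair_icc - interaction_apoe^2 - interaction_afqt^2
  if (resid_var <= 0.05) {
    stop("infeasible variance decomposition: effect sizes plus pair_icc ",
         "leave no residual EF variance")
  }
  cfg$resid_var <- resid_var
  structure(cfg, class = "sim_config")
}

# cohort-level node propensity profile for a timepoint stream
node_profile <- function(cfg, stream) {
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(derive_seed(cfg$seed, stream))
  stats::rlnorm(cfg$n_nodes, 0, cfg$strength_sdlog)
}

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# one symmetric nonnegative integer count matrix given a node profile
sim_count_matrix <- function(cfg, profile, rngseed) {
  set.seed(rngseed)
  n <- cfg$n_nodes
  p <- profile * exp(stats::rnorm(n, 0, cfg$subject_sdlog))
  mu <- cfg$base_count * tcrossprod(p) / mean(p)^2
  ut <- upper.tri(mu)
  m <- sum(ut)
  present <- stats::rbinom(m, 1, cfg$density)
  counts <- present * (1 + stats::rpois(m, mu[ut]))
  W <- matrix(0, n, n)
  W[ut] <- counts
  W + t(W)
}

#' Simulate one streamline-count connectome
#'
#' Deterministic given (config seed, subject_seed): child seeds are
#' derived by the counter-based scheme in [derive_seed()], with no
#' dependence on (and no lasting effect on) the global RNG state.
#'
#' @param cfg a [sim_config()].
#' @param subject_seed integer subject counter.
#' @param timepoint label for the returned object.
#' @return a [connectome] with symmetric nonnegative integer counts and a
#'   zero diagonal.
#' @export
simulate_connectome <- function(cfg, subject_seed, timepoint = "T1") {
  stopifnot(inherits(cfg, "sim_config"))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  W <- sim_count_matrix(cfg, node_profile(cfg, 1),
                        derive_seed(cfg$seed, 10, subject_seed))
  connectome(W, seq_len(cfg$n_nodes),
             subject_id = sprintf("S%03d", subject_seed),
             timepoint = timepoint)
}

#' Simulate a subject's Time 1 / Time 2 connectome pair
#'
#' Time 2 is an edge-wise mix of the Time 1 matrix and a fresh matrix
#' drawn from an independent cohort-level node profile:
#' `W2 = round(s * W1 + (1 - s) * F)` with `s = timepoint_stability`.
#' At s = 1 the two matrices are identical; at s = 0 the Time 2 group
#' topography is unrelated to Time 1.
#'
#' @inheritParams simulate_connectome
#' @return list with elements `T1` and `T2` ([connectome]s).
#' @export
simulate_timepoint_pair <- function(cfg, subject_seed) {
  stopifnot(inherits(cfg, "sim_config"))
  s <- cfg$timepoint_stability
  if (s < 0 || s > 1) stop("timepoint_stability must lie in [0, 1]")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  W1 <- sim_count_matrix(cfg, node_profile(cfg, 1),
                         derive_seed(cfg$seed, 10, subject_seed))
  Wf <- sim_count_matrix(cfg, node_profile(cfg, 2),
                         derive_seed(cfg$seed, 20, subject_seed))
  W2 <- round(s * W1 + (1 - s) * Wf)
  sid <- sprintf("S%03d", subject_seed)
  list(
    T1 = connectome(W1, seq_len(cfg$n_nodes), subject_id = sid,
                    timepoint = "T1"),
    T2 = connectome(W2, seq_len(cfg$n_nodes), subject_id = sid,
                    timepoint = "T2")
  )
}

#' Synthetic atlas network-membership table
#'
#' Assigns every parcel a base network label (control, salience, and a
#' rotation of the remaining canonical networks), then adds
#' `multiple_demand` membership rows for the frontoparietal core of the
#' control network plus half of the salience parcels — so the two
#' networks of interest overlap, as in the real atlas. At 400 parcels the
#' control network has exactly 61 members.
#'
#' @param n_parcels number of parcels.
#' @return a [network_definition].
#' @export
make_network_definition <- function(n_parcels) {
  n_c <- ceiling(0.1525 * n_parcels)
  n_s <- ceiling(0.08 * n_parcels)
  others <- c("default", "dorsal_attention", "visual", "somatomotor",
              "limbic", "temporal_parietal")
  base <- c(rep("control", n_c), rep("salience", n_s),
            rep(others, length.out = n_parcels - n_c - n_s))
  ids <- seq_len(n_parcels)
  tab <- data.frame(
    parcel_id = ids,
    parcel_name = sprintf("Parcel_%03d_%s", ids, base),
    network_label = base
  )
  md_ids <- c(ids[seq_len(ceiling(0.7 * n_c))],
              ids[n_c + seq_len(ceiling(0.5 * n_s))])
  md <- data.frame(
    parcel_id = md_ids,
    parcel_name = tab$parcel_name[md_ids],
    network_label = "multiple_demand"
  )
  network_definition(rbind(tab, md))
}

# network means via the real controllability code path
cohort_network_means <- function(C, nd) {
  P <- modal_controllability(normalize_connectome(C))
  c(control = network_mean_controllability(P, nd, "control"),
    multiple_demand = network_mean_controllability(P, nd, "multiple_demand"))
}

#' Simulate a twin-structured two-timepoint cohort
#'
#' Generates per-subject connectomes, pushes them through the actual
#' controllability pipeline (normalization, modal controllability,
#' network means) and builds a latent executive-function score
#'
#'   EF = beta_true * z(mc) + gamma_health * z(health) +
#'        gamma_afqt * z(probit AFQT) + pair intercept + noise,
#'
#' with the pair-intercept variance set by `pair_icc` and the residual
#' variance closing the decomposition to 1. Time 2 subtracts a decline
#' whose between-person part couples to the subject's controllability
#' change at `delta_coupling`. The six raw task scores are emitted by
#' inverting the phenotype module's scoring conventions (trail-making is
#' emitted as times so that scoring negates it back), so the full scoring
#' path is exercised on the way back in.
#'
#' @param cfg a [sim_config()].
#' @param keep_connectomes retain the connectome objects in the result
#'   (set FALSE in replicate loops to save memory; they are still
#'   generated and analyzed).
#' @return list with `phenotype` (long table, one row per
#'   subject-timepoint), `network_means` (subject_id, timepoint,
#'   mc_control, mc_multiple_demand), `network_definition`, `connectomes`
#'   (named list, or NULL), and `truth` (ground-truth parameters and
#'   latent scores).
#' @export
simulate_cohort <- function(cfg, keep_connectomes = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  n_sub <- 2 * cfg$n_pairs + cfg$n_singletons
  sid <- sprintf("S%03d", seq_len(n_sub))
  pair <- sprintf("P%03d", c(rep(seq_len(cfg$n_pairs), each = 2),
                             cfg$n_pairs + seq_len(cfg$n_singletons)))
  nd <- make_network_definition(cfg$n_nodes)
  two_tp <- cfg$timepoints == "both"

  # covariates
  set.seed(derive_seed(cfg$seed, 30))
  age1 <- stats::rnorm(n_sub, cfg$age_mean, cfg$age_sd)
  race <- stats::rbinom(n_sub, 1, cfg$white_prevalence)
  afqt_g <- stats::rnorm(n_sub, cfg$afqt_mean_z, cfg$afqt_sd_z)
  afqt_pct <- pmin(pmax(100 * stats::pnorm(afqt_g), 0.5), 99.5)
  apoe <- stats::rbinom(n_sub, 1, cfg$apoe_prevalence)
  health1 <- pmin(stats::rpois(n_sub, cfg$health_rate), 6L)
  health2 <- pmin(health1 + stats::rbinom(n_sub, 1, cfg$health_worsen_prob), 6L)

  # connectomes and network means through the real pipeline
  conns <- list()
  mc1 <- matrix(NA_real_, n_sub, 2,
                dimnames = list(NULL, c("control", "multiple_demand")))
  mc2 <- mc1
  for (i in seq_len(n_sub)) {
    if (two_tp) {
      cp <- simulate_timepoint_pair(cfg, i)
      mc1[i, ] <- cohort_network_means(cp$T1, nd)
      mc2[i, ] <- cohort_network_means(cp$T2, nd)
      if (keep_connectomes) {
        conns[[paste0(sid[i], "_T1")]] <- cp$T1
        conns[[paste0(sid[i], "_T2")]] <- cp$T2
      }
    } else {
      C <- simulate_connectome(cfg, i)
      mc1[i, ] <- cohort_network_means(C, nd)
      if (keep_connectomes) conns[[paste0(sid[i], "_T1")]] <- C
    }
  }

  # latent executive function
  set.seed(derive_seed(cfg$seed, 31))
  drv <- cfg$driver_network
  X1 <- zscore(mc1[, drv])
  G <- zscore(stats::qnorm(afqt_pct / 100))
  H1 <- zscore(cap_health(health1))
  u <- stats::rnorm(cfg$n_pairs + cfg$n_singletons)
  pair_idx <- match(pair, unique(pair))
  ef1 <- cfg$beta_true * X1 +
    cfg$interaction_apoe * X1 * apoe +
    cfg$interaction_afqt * X1 * G +
    cfg$gamma_health * H1 + cfg$gamma_afqt * G +
    sqrt(cfg$pair_icc) * u[pair_idx] +
    sqrt(cfg$resid_var) * stats::rnorm(n_sub)
  if (two_tp) {
    rem <- 1 - cfg$delta_coupling^2 - cfg$pair_icc
    if (rem <= 0) stop("infeasible variance decomposition for the decline")
    dX <- zscore(mc1[, drv] - mc2[, drv])
    u2 <- stats::rnorm(cfg$n_pairs + cfg$n_singletons)
    decline <- cfg$mean_decline + cfg$decline_sd *
      (cfg$delta_coupling * dX + sqrt(cfg$pair_icc) * u2[pair_idx] +
         sqrt(rem) * stats::rnorm(n_sub))
    ef2 <- ef1 - decline
  }

  pheno1 <- data.frame(
    subject_id = sid, timepoint = "T1", twin_pair_id = pair,
    age = round(age1, 2), race_ethnicity = race,
    afqt_pctile = round(afqt_pct, 2), apoe_e4 = apoe, health = health1,
    task_scores_from_latent(ef1, cfg, derive_seed(cfg$seed, 40))
  )
  pheno <- pheno1
  if (two_tp) {
    pheno2 <- data.frame(
      subject_id = sid, timepoint = "T2", twin_pair_id = pair,
      age = round(age1 + cfg$follow_up_years, 2), race_ethnicity = race,
      afqt_pctile = round(afqt_pct, 2), apoe_e4 = apoe, health = health2,
      task_scores_from_latent(ef2, cfg, derive_seed(cfg$seed, 41))
    )
    pheno <- rbind(pheno1, pheno2)
  }

  nm <- data.frame(
    subject_id = rep(sid, if (two_tp) 2 else 1),
    timepoint = rep(c("T1", if (two_tp) "T2"), each = n_sub),
    mc_control = c(mc1[, "control"], if (two_tp) mc2[, "control"]),
    mc_multiple_demand = c(mc1[, "multiple_demand"],
                           if (two_tp) mc2[, "multiple_demand"])
  )

  list(
    phenotype = pheno,
    network_means = nm,
    network_definition = nd,
    connectomes = if (keep_connectomes) conns else NULL,
    truth = list(
      beta_true = cfg$beta_true, pair_icc = cfg$pair_icc,
      delta_coupling = cfg$delta_coupling, loadings = cfg$loadings,
      seed = cfg$seed, driver_network = drv,
      ef_latent_t1 = ef1, ef_latent_t2 = if (two_tp) ef2 else NULL
    )
  )
}

# invert the scoring conventions: emit raw task scores whose residualized,
# oriented, z-scored versions load on the latent EF at cfg$loadings
task_scores_from_latent <- function(ef, cfg, rngseed) {
  set.seed(rngseed)
  n <- length(ef)
  lam <- cfg$loadings
  ind <- vapply(lam, function(l) l * ef + sqrt(1 - l^2) * stats::rnorm(n),
                numeric(n))
  zw <- stats::rnorm(n); zc <- stats::rnorm(n)
  zs <- stats::rnorm(n); zf <- stats::rnorm(n)
  word <- round(90 + 10 * zw)
  color <- round(70 + 8 * zc)
  single <- pmax(round(25 + 5 * zs, 1), 5)
  fluency <- pmax(round(40 + 8 * zf), 0)
  data.frame(
    stroop_colorword = pmax(round(40 + 0.25 * (word - 90) +
                                    0.2 * (color - 70) + 6 * ind[, 1]), 0),
    stroop_word = word,
    stroop_color = color,
    trails_switch_time = pmax(round(60 + 0.9 * (single - 25) -
                                      12 * ind[, 2], 1), 10),
    trails_single_time = single,
    catswitch_correct_switches = pmax(round(12 + 0.25 * (fluency - 40) +
                                              3 * ind[, 3]), 0),
    catfluency_correct = fluency,
    letter_number_total = pmax(round(14 + 3 * ind[, 4]), 0),
    reading_span_total = pmax(round(40 + 8 * ind[, 5]), 0),
    digit_span_total = pmax(round(16 + 4 * ind[, 6]), 0)
  )
}

#' Write the deterministic fixture suite
#'
#' A small, fully deterministic dataset for unit tests and documentation:
#' 3 subjects (one twin pair + one singleton) at 2 timepoints with 20-node
#' connectomes, written as dense TSVs next to the phenotype table, the
#' network definition, and a ground-truth JSON. Byte-identical across
#' runs for a given seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed (default 101).
#' @return character vector of written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(n_nodes = 20, n_pairs = 1, n_singletons = 1,
                    seed = seed)
  cohort <- simulate_cohort(cfg)
  files <- character(0)
  for (nm in names(cohort$connectomes)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_matrix(cohort$connectomes[[nm]], path, format = "dense")
    files <- c(files, path)
  }
  ppath <- file.path(out_dir, "phenotype.tsv")
  write_tsv_file(cohort$phenotype, ppath)
  npath <- file.path(out_dir, "network_definition.tsv")
  write_network_definition(cohort$network_definition, npath)
  tpath <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(beta_true = cfg$beta_true, pair_icc = cfg$pair_icc,
         delta_coupling = cfg$delta_coupling, loadings = cfg$loadings,
         seed = cfg$seed),
    tpath, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, ppath, npath, tpath))
}

# deterministic TSV writer (bytewise stable across runs)
write_tsv_file <- function(df, path) {
  fmt <- function(x) {
    if (is.numeric(x)) {
      ifelse(is.na(x), "NA",
             ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                    formatC(x, digits = 15, format = "g")))
    } else as.character(x)
  }
  cols <- lapply(df, fmt)
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
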