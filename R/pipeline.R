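# End-to-end orchestration: load connectomes, derive controllability and
# executive-function scores, fit the association models, write outputs and
# a reproducible run manifest.

#' Assemble the analysis table for one timepoint
#'
#' Scores the wave: builds the six EF indicators from that timepoint's
#' task scores, scores the common factor, probit-transforms and z-scores
#' AFQT percentiles, caps the health index, and merges the network-level
#' controllability means.
#'
#' @param phenotype long phenotype table (one row per subject-timepoint)
#'   with the ten task columns plus `subject_id`, `timepoint`,
#'   `twin_pair_id`, `age`, `race_ethnicity`, `afqt_pctile`, `apoe_e4`,
#'   `health`.
#' @param network_means data.frame with `subject_id`, `timepoint`,
#'   `mc_control`, `mc_multiple_demand`.
#' @param timepoint `"T1"` or `"T2"`.
#' @param loadings optional fixed factor loadings (see
#'   [ef_factor_score()]).
#' @return data.frame with `ef`, `mc_*`, covariates and ids; one row per
#'   subject. The indicator columns are attached as attribute
#'   `"indicators"`.
#' @export
assemble_analysis_table <- function(phenotype, network_means,
                                    timepoint = "T1", loadings = NULL) {
  ph <- phenotype[phenotype$timepoint == timepoint, , drop = FALSE]
  if (nrow(ph) == 0) stop("no phenotype rows at timepoint ", timepoint)
  ind <- build_indicators(ph)
  fs <- ef_factor_score(ind, loadings = loadings)
  nm <- network_means[network_means$timepoint == timepoint, , drop = FALSE]
  out <- data.frame(
    subject_id = ph$subject_id,
    timepoint = timepoint,
    twin_pair_id = ph$twin_pair_id,
    ef = fs$scores,
    age = ph$age,
    race_ethnicity = ph$race_ethnicity,
    health = cap_health(ph$health),
    afqt_z = probit_z(ph$afqt_pctile),
    apoe_e4 = ph$apoe_e4
  )
  m <- match(out$subject_id, nm$subject_id)
  out$mc_control <- nm$mc_control[m]
  out$mc_multiple_demand <- nm$mc_multiple_demand[m]
  attr(out, "indicators") <- ind
  attr(out, "loadings") <- fs$loadings
  out
}

default_config <- function() {
  list(
    paths = list(connectome_dir = NULL, connectome_format = "dense",
                 phenotype = NULL, network_definition = NULL,
                 out_dir = NULL),
    networks = c("control", "multiple_demand"),
    analyses = list(cross_sectional = TRUE, longitudinal = TRUE,
                    moderation = list()),
    fdr_families = NULL,
    outlier_sd = 3,
    min_n = 20,
    factor = list(loadings = NULL),
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a config list; merges it over the
#' defaults and collects every schema violation rather than stopping at
#' the first.
#'
#' @param x path to a YAML/JSON config or a list.
#' @return list with `config` (merged) and `errors` (character vector;
#'   empty when valid).
#' @export
validate_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("unreadable config file: ", x)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a list or a YAML/JSON path")
  merge_config <- function(base, user) {
    for (nm in names(user)) {
      if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
          !is.null(names(user[[nm]]))) {
        base[[nm]] <- merge_config(base[[nm]], user[[nm]])
      } else {
        base[[nm]] <- user[[nm]]
      }
    }
    base
  }
  cfg <- merge_config(default_config(), x)
  errors <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  for (key in c("connectome_dir", "phenotype", "network_definition",
                "out_dir")) {
    need(!is.null(cfg$paths[[key]]), paste0("missing paths$", key))
  }
  for (key in c("connectome_dir", "phenotype", "network_definition")) {
    p <- cfg$paths[[key]]
    if (!is.null(p)) need(file.exists(p), paste0("paths$", key,
                                                 " does not exist: ", p))
  }
  need(cfg$paths$connectome_format %in% c("dense", "edgelist"),
       "paths$connectome_format must be 'dense' or 'edgelist'")
  need(is.numeric(cfg$outlier_sd) && cfg$outlier_sd > 0,
       "outlier_sd must be a positive number")
  need(is.numeric(cfg$min_n) && cfg$min_n >= 3, "min_n must be >= 3")
  if (!is.null(cfg$factor$loadings)) {
    need(length(cfg$factor$loadings) == 6 &&
           all(abs(cfg$factor$loadings) < 1),
         "factor$loadings must be 6 values in (-1, 1)")
  }
  # analysis ids that this config will produce
  ids <- c(
    if (isTRUE(cfg$analyses$cross_sectional)) {
      as.vector(outer(paste0("cs_", cfg$networks), c("T1", "T2"),
                      paste, sep = "_"))
    },
    if (isTRUE(cfg$analyses$longitudinal)) {
      paste0("long_", cfg$networks)
    },
    unlist(lapply(cfg$analyses$moderation, function(mod) {
      as.vector(outer(paste0("mod_", mod, "_", cfg$networks),
                      c("T1", "T2"), paste, sep = "_"))
    }))
  )
  if (is.null(cfg$fdr_families)) {
    # default family: the cross-sectional network tests across timepoints
    cfg$fdr_families <- list(
      cross_sectional = grep("^cs_", ids, value = TRUE)
    )
  }
  for (fam in names(cfg$fdr_families)) {
    unknown <- setdiff(cfg$fdr_families[[fam]], ids)
    need(length(unknown) == 0,
         paste0("fdr family '", fam, "' references undefined analysis id(s): ",
                paste(unknown, collapse = ", ")))
  }
  list(config = cfg, errors = errors)
}

# rolling polynomial hash of the serialized config, for the manifest
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                      null = "null", digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load connectomes, normalize, compute
#' per-parcel modal controllability, average over the networks of
#' interest, flag network-level outliers (|z| > `outlier_sd` per
#' timepoint), score the EF phenotype, fit cross-sectional models per
#' network and timepoint, apply BH-FDR over the configured families, fit
#' longitudinal difference models, fit moderation models, and compute
#' topography maps and their between-timepoint similarity. All outputs
#' are TSV/JSON files under `paths$out_dir`; analysis blocks whose
#' preconditions fail (e.g. a single timepoint of data, or too few rows)
#' are skipped with the reason recorded in the manifest.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @return the run manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  v <- validate_config(config)
  if (length(v$errors) > 0) {
    stop("invalid config:\n  ", paste(v$errors, collapse = "\n  "))
  }
  cfg <- v$config
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  outputs <- character(0)
  skipped <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_file(df, path)
    outputs <<- c(outputs, name)
  }
  emit_json <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    outputs <<- c(outputs, name)
  }

  # --- load inputs -----------------------------------------------------------
  nd <- read_network_definition(cfg$paths$network_definition)
  pheno <- utils::read.delim(cfg$paths$phenotype)
  files <- sort(list.files(cfg$paths$connectome_dir,
                           pattern = "_T[12]\\.tsv$", full.names = TRUE))
  if (length(files) == 0) {
    stop("no connectome files (*_T1.tsv / *_T2.tsv) in ",
         cfg$paths$connectome_dir)
  }
  conns <- lapply(files, read_connectome,
                  format = cfg$paths$connectome_format)
  log$loaded <- list(connectomes = length(conns), phenotype_rows = nrow(pheno))

  # --- controllability -------------------------------------------------------
  profiles <- lapply(conns, function(C) {
    modal_controllability(normalize_connectome(C))
  })
  parcel_tab <- do.call(rbind, lapply(profiles, function(P) {
    data.frame(subject_id = P$subject_id, timepoint = P$timepoint,
               parcel_id = P$parcel_ids, phi = unname(P$phi))
  }))
  emit(parcel_tab, "controllability_parcels.tsv")
  nm <- do.call(rbind, lapply(profiles, function(P) {
    row <- data.frame(subject_id = P$subject_id, timepoint = P$timepoint)
    for (net in cfg$networks) {
      row[[paste0("mc_", net)]] <- network_mean_controllability(P, nd, net)
    }
    row
  }))
  net_long <- do.call(rbind, lapply(cfg$networks, function(net) {
    data.frame(subject_id = nm$subject_id, timepoint = nm$timepoint,
               network_label = net, mean_phi = nm[[paste0("mc_", net)]])
  }))
  emit(net_long, "controllability_networks.tsv")

  # --- outlier flags (per network per timepoint) -----------------------------
  nm$outlier <- FALSE
  for (tp in unique(nm$timepoint)) {
    for (net in cfg$networks) {
      sel <- nm$timepoint == tp
      if (sum(sel) >= 3) {
        flags <- flag_outliers(nm[[paste0("mc_", net)]][sel],
                               threshold = cfg$outlier_sd)
        nm$outlier[sel] <- nm$outlier[sel] | flags
      }
    }
  }
  log$outliers_flagged <- sum(nm$outlier)

  # --- phenotype scoring -----------------------------------------------------
  timepoints <- intersect(c("T1", "T2"), unique(pheno$timepoint))
  tables <- list()
  for (tp in timepoints) {
    tab <- tryCatch(
      assemble_analysis_table(pheno, nm, timepoint = tp,
                              loadings = cfg$factor$loadings),
      error = function(e) {
        skipped[[paste0("scores_", tp)]] <<- conditionMessage(e)
        NULL
      }
    )
    if (is.null(tab)) next
    tables[[tp]] <- tab
    ind <- attr(tab, "indicators")
    emit(cbind(data.frame(subject_id = tab$subject_id, timepoint = tp),
               ind,
               data.frame(ef_score = tab$ef, afqt_z = tab$afqt_z,
                          health_capped = tab$health)),
         paste0("scores_", tp, ".tsv"))
  }

  # --- models ----------------------------------------------------------------
  model_pvals <- list()
  run_model <- function(id, fun) {
    res <- tryCatch(fun(), error = function(e) {
      skipped[[id]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(res)) return(invisible(NULL))
    emit(cbind(analysis_id = id, res$terms), paste0("model_", id, ".tsv"))
    emit_json(list(analysis_id = id, descriptor = res$descriptor,
                   sigma2_pair = res$sigma2_pair,
                   sigma2_resid = res$sigma2_resid, n_obs = res$n_obs,
                   n_pairs = res$n_pairs, singular = res$singular,
                   df_method = res$df_method),
              paste0("model_", id, ".json"))
    model_pvals[[id]] <<- model_term(res)$p
    invisible(NULL)
  }

  excl <- nm$subject_id[nm$outlier]
  if (isTRUE(cfg$analyses$cross_sectional)) {
    for (tp in names(tables)) {
      tab <- tables[[tp]]
      tab <- tab[!tab$subject_id %in% excl, , drop = FALSE]
      for (net in cfg$networks) {
        run_model(paste0("cs_", net, "_", tp), function() {
          fit_lmm(tab, dv = "ef", iv = paste0("mc_", net),
                  covariates = c("age", "race_ethnicity", "health",
                                 "afqt_z"),
                  min_n = cfg$min_n)
        })
      }
    }
  }

  if (isTRUE(cfg$analyses$longitudinal)) {
    if (length(tables) == 2) {
      change <- make_change_table(rbind(tables$T1[names(tables$T1)],
                                        tables$T2[names(tables$T2)]))
      change <- change[!change$subject_id %in% excl, , drop = FALSE]
      for (net in cfg$networks) {
        run_model(paste0("long_", net), function() {
          fit_longitudinal_change(change, network = net,
                                  min_n = cfg$min_n)
        })
      }
    } else {
      skipped$longitudinal <- "only one timepoint of data"
    }
  }

  for (mod in cfg$analyses$moderation) {
    for (tp in names(tables)) {
      tab <- tables[[tp]]
      tab <- tab[!tab$subject_id %in% excl, , drop = FALSE]
      for (net in cfg$networks) {
        run_model(paste0("mod_", mod, "_", net, "_", tp), function() {
          fit_moderation(tab, iv = paste0("mc_", net), moderator = mod,
                         min_n = cfg$min_n)
        })
      }
    }
  }

  # --- FDR over configured families ------------------------------------------
  for (fam in names(cfg$fdr_families)) {
    ids <- intersect(cfg$fdr_families[[fam]], names(model_pvals))
    if (length(ids) == 0) next
    p <- unlist(model_pvals[ids])
    emit(data.frame(analysis_id = ids, p = unname(p),
                    p_fdr = bh_adjust(unname(p))),
         paste0("fdr_", fam, ".tsv"))
  }

  # --- topography ------------------------------------------------------------
  topo <- list()
  for (tp in timepoints) {
    ps <- profiles[vapply(profiles, function(P) P$timepoint == tp, TRUE)]
    if (length(ps) == 0) next
    topo[[tp]] <- group_topography(ps)
    emit(data.frame(parcel_id = topo[[tp]]$parcel_id,
                    group_mean_phi = topo[[tp]]$mean_phi,
                    rank = topo[[tp]]$rank),
         paste0("topography_", tp, ".tsv"))
  }
  if (length(topo) == 2) {
    sim <- topography_similarity(topo$T1, topo$T2)
    emit_json(sim, "topography_similarity.json")
  } else {
    skipped$topography_similarity <- "need both timepoints"
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("efcontrol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    log = log,
    excluded_outliers = as.list(unique(excl)),
    skipped = skipped,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
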