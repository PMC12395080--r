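#' Study configuration
#'
#' Bundles everything a full analysis run needs: the input mode (simulate a
#' synthetic cohort, or read EDF files listed in a cohort CSV), preprocessing
#' settings, statistics settings and the mandatory master seed.
#'
#' @param mode `"simulate"` or `"edf"`.
#' @param cohort a [cohort_spec()] (simulate mode).
#' @param edf_dir,cohort_csv EDF directory and cohort table path (edf mode).
#'   The CSV must have columns subject_id, site, etiology, delirium, age,
#'   file; per-site epoch policies are applied on read.
#' @param exclude_channels channels dropped before analysis.
#' @param epoch_policies named list (per site) of [epoch_policy()] settings
#'   used in edf mode; defaults: sites A/B take 10 random clean epochs,
#'   site C the first 4.
#' @param n_boot bootstrap iterations for descriptive CIs.
#' @param conf_level confidence level.
#' @param edge_trim_s PLI edge trim in seconds.
#' @param leave_site_out site excluded in the default sensitivity analysis.
#' @param seed master seed (mandatory).
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "edf"),
                         cohort = default_cohort_spec(),
                         edf_dir = NULL, cohort_csv = NULL,
                         exclude_channels = c("A1", "A2", "Fp1", "Fp2"),
                         epoch_policies = NULL,
                         n_boot = 1000, conf_level = 0.95,
                         edge_trim_s = 0.5,
                         leave_site_out = "C",
                         seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) {
    stop("a master seed is mandatory: runs must be reproducible", call. = FALSE)
  }
  if (mode == "edf" && (is.null(edf_dir) || is.null(cohort_csv))) {
    stop("edf mode requires 'edf_dir' and 'cohort_csv'", call. = FALSE)
  }
  structure(list(mode = mode, cohort = cohort, edf_dir = edf_dir,
                 cohort_csv = cohort_csv, exclude_channels = exclude_channels,
                 epoch_policies = epoch_policies, n_boot = n_boot,
                 conf_level = conf_level, edge_trim_s = edge_trim_s,
                 leave_site_out = leave_site_out, seed = as.integer(seed)),
            class = "study_config")
}

default_epoch_policies <- function(seed) {
  list(
    A = list(n_epochs = 10L, selection = "random_among_clean"),
    B = list(n_epochs = 10L, selection = "random_among_clean"),
    C = list(n_epochs = 4L, selection = "first_clean")
  )
}

preprocess_recording <- function(rec, config) {
  drop <- intersect(config$exclude_channels, rec$channel_labels)
  if (length(drop)) rec <- exclude_channels(rec, drop)
  average_reference(rec)
}

# feature table: one row per subject, streamed so recordings are never all
# held in memory at once
compute_feature_table <- function(config) {
  if (config$mode == "simulate") {
    plan <- cohort_plan(config$cohort, config$seed)
    tab <- plan$table
    feats <- lapply(seq_len(nrow(tab)), function(i) {
      rec <- simulate_subject(plan$params[[tab$subject_id[i]]], seed = tab$seed[i])
      rec <- preprocess_recording(rec, config)
      extract_features(rec, edge_trim_s = config$edge_trim_s)
    })
    cohort <- tab[, c("subject_id", "site", "etiology", "delirium", "age", "n_epochs")]
  } else {
    cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    need <- c("subject_id", "site", "etiology", "delirium", "age", "file")
    if (!all(need %in% names(cohort))) {
      stop("cohort CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
    }
    cohort$delirium <- as.logical(cohort$delirium)
    policies <- config$epoch_policies
    if (is.null(policies)) policies <- default_epoch_policies(config$seed)
    feats <- lapply(seq_len(nrow(cohort)), function(i) {
      rec <- read_edf(file.path(config$edf_dir, cohort$file[i]))
      pol_cfg <- policies[[cohort$site[i]]]
      if (is.null(pol_cfg)) stop("no epoch policy for site ", cohort$site[i], call. = FALSE)
      pol <- epoch_policy(pol_cfg$n_epochs,
                          epoch_len = pol_cfg$epoch_len %||% 8,
                          selection = pol_cfg$selection,
                          seed = derive_seed(config$seed, "epoch_select",
                                             cohort$subject_id[i]))
      drop <- intersect(config$exclude_channels, rec$channel_labels)
      if (length(drop)) rec <- exclude_channels(rec, drop)
      rec <- select_epochs(rec, pol)
      rec <- average_reference(rec)
      rec$meta$subject_id <- cohort$subject_id[i]
      extract_features(rec, edge_trim_s = config$edge_trim_s)
    })
    cohort$n_epochs <- vapply(cohort$site, function(s) {
      as.integer(policies[[s]]$n_epochs)
    }, integer(1))
    cohort <- cohort[, c("subject_id", "site", "etiology", "delirium", "age", "n_epochs")]
  }
  features <- do.call(rbind, feats)
  # feats rows are in cohort order by construction
  cbind(cohort, features[, setdiff(names(features), "subject_id"), drop = FALSE])
}

subgroup_id <- function(site, etiology) paste(site, etiology, sep = ":")

# per-feature x subgroup effects and descriptives
compute_subgroup_table <- function(features, config) {
  sg_keys <- unique(features[, c("site", "etiology")])
  rows <- list()
  for (feat in feature_names()) {
    for (i in seq_len(nrow(sg_keys))) {
      site <- sg_keys$site[i]; etio <- sg_keys$etiology[i]
      sub <- features[features$site == site & features$etiology == etio, ]
      x_del <- sub[[feat]][sub$delirium]
      x_ctrl <- sub[[feat]][!sub$delirium]
      if (length(x_del) < 2 || length(x_ctrl) < 2) {
        warning(sprintf("subgroup %s dropped for %s: fewer than 2 subjects in an arm",
                        subgroup_id(site, etio), feat), call. = FALSE)
        next
      }
      eff <- hedges_g(x_del, x_ctrl, conf_level = config$conf_level)
      b_del <- bootstrap_mean_ci(x_del, n_boot = config$n_boot,
                                 level = config$conf_level,
                                 seed = derive_seed(config$seed, "boot", feat,
                                                    site, etio, "del"))
      b_ctrl <- bootstrap_mean_ci(x_ctrl, n_boot = config$n_boot,
                                  level = config$conf_level,
                                  seed = derive_seed(config$seed, "boot", feat,
                                                     site, etio, "ctrl"))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, subgroup = subgroup_id(site, etio),
        site = site, etiology = etio,
        n_del = eff$n_del, n_ctrl = eff$n_ctrl,
        mean_del = b_del$mean, ci_lo_del = b_del$ci_lo, ci_hi_del = b_del$ci_hi,
        sd_del = stats::sd(x_del),
        mean_ctrl = b_ctrl$mean, ci_lo_ctrl = b_ctrl$ci_lo, ci_hi_ctrl = b_ctrl$ci_hi,
        sd_ctrl = stats::sd(x_ctrl),
        g = eff$g, var_g = eff$var_g, ci_lo = eff$ci_lo, ci_hi = eff$ci_hi,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

pool_from_subgroups <- function(subgroups, config, exclude_site = NULL) {
  rows <- list()
  for (feat in feature_names()) {
    sub <- subgroups[subgroups$feature == feat, ]
    if (!is.null(exclude_site)) sub <- sub[sub$site != exclude_site, ]
    if (nrow(sub) < 2) {
      stop(sprintf("fewer than 2 subgroups remain for '%s': cannot pool", feat),
           call. = FALSE)
    }
    fit <- rema(sub$g, sub$var_g, labels = sub$subgroup,
                conf_level = config$conf_level)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = feat, k = fit$k, pooled_g = fit$b, se = fit$se,
      ci_lo = fit$ci_lo, ci_hi = fit$ci_hi, pval = fit$pval,
      tau2 = fit$tau2, Q = fit$Q, df = fit$df, p_Q = fit$p_Q, I2 = fit$I2,
      weights = paste(sprintf("%s=%.4f", fit$labels, fit$weights), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

compute_status_heterogeneity <- function(subgroups) {
  rows <- list()
  for (feat in feature_names()) {
    sub <- subgroups[subgroups$feature == feat, ]
    for (status in c("delirious", "non-delirious")) {
      if (status == "delirious") {
        h <- status_heterogeneity(sub$mean_del, sub$sd_del, sub$n_del)
      } else {
        h <- status_heterogeneity(sub$mean_ctrl, sub$sd_ctrl, sub$n_ctrl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, status = status, I2 = h$I2, Q = h$Q, df = h$df,
        p = h$p, tau2 = h$tau2, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

compute_age_regression <- function(features) {
  rows <- list()
  for (feat in feature_names()) {
    cf <- age_adjusted_effect(features[[feat]], features$delirium, features$age)
    st <- cf[cf$term == "status", ]; ag <- cf[cf$term == "age", ]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = feat,
      status_estimate = st$estimate, status_se = st$se, status_p = st$p,
      age_estimate = ag$estimate, age_se = ag$se, age_p = ag$p,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Run the full multicenter analysis
#'
#' Executes the fixed stage order: obtain per-subject epoched recordings
#' (simulated or read from EDF), preprocess (channel exclusion, epoch
#' selection, average reference), extract the nine qEEG features, then for
#' every feature compute per-subgroup descriptives (bootstrap CIs) and
#' Hedges' g, pool across the five etiology-by-site subgroups with the REML
#' random-effects model, quantify status-stratified heterogeneity, fit the
#' age-adjusted regression, and run the leave-site-out sensitivity analysis.
#' All randomness descends from the config's master seed via labelled
#' substreams, so results are byte-identical across runs.
#'
#' @param config a [study_config()].
#' @return An object of class `qeeg_study` with tables `features`,
#'   `subgroups`, `pooled`, `heterogeneity`, `age_regression`, `sensitivity`
#'   and the `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  features <- compute_feature_table(config)
  subgroups <- compute_subgroup_table(features, config)
  pooled <- pool_from_subgroups(subgroups, config)
  heterogeneity <- compute_status_heterogeneity(subgroups)
  age_regression <- compute_age_regression(features)
  sensitivity <- list()
  if (!is.null(config$leave_site_out) && !is.na(config$leave_site_out)) {
    site <- config$leave_site_out
    if (site %in% subgroups$site && length(unique(subgroups$site)) >= 2) {
      sensitivity[[site]] <- pool_from_subgroups(subgroups, config,
                                                 exclude_site = site)
    }
  }
  structure(list(features = features, subgroups = subgroups, pooled = pooled,
                 heterogeneity = heterogeneity, age_regression = age_regression,
                 sensitivity = sensitivity, config = config),
            class = "qeeg_study")
}

#' Leave-one-site-out sensitivity re-pooling
#'
#' Re-pools every feature using only the subgroups from the remaining sites,
#' re-estimating the between-study variance.
#'
#' @param study a fitted `qeeg_study`.
#' @param site site identifier to exclude.
#' @return A pooled table (same shape as `study$pooled`).
#' @export
leave_site_out <- function(study, site) {
  stopifnot(inherits(study, "qeeg_study"))
  remaining <- setdiff(unique(study$subgroups$site), site)
  if (length(remaining) < 2) {
    stop("fewer than 2 sites would remain after exclusion", call. = FALSE)
  }
  pool_from_subgroups(study$subgroups, study$config, exclude_site = site)
}

#' @export
print.qeeg_study <- function(x, ...) {
  cat(sprintf("<qeeg_study> %d subjects (%d delirious / %d non-delirious), %d subgroup(s)\n",
              nrow(x$features), sum(x$features$delirium), sum(!x$features$delirium),
              length(unique(x$subgroups$subgroup))))
  cat("Pooled random-effects SMDs (delirious - non-delirious):\n")
  tab <- x$pooled[, c("feature", "pooled_g", "ci_lo", "ci_hi", "tau2", "I2", "p_Q")]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.qeeg_study <- function(object, ...) {
  print(object)
  cat("\nStatus-stratified heterogeneity (I^2, %):\n")
  wide <- stats::reshape(object$heterogeneity[, c("feature", "status", "I2")],
                         idvar = "feature", timevar = "status",
                         direction = "wide")
  print(wide, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Write all result tables of a study run
#'
#' Emits the per-subject feature table, subgroup effects, pooled effects,
#' status heterogeneity, age regression and sensitivity tables as CSV files,
#' plus a JSON run manifest (seed, package version, config checksum) that
#' makes a re-run reproducible.
#'
#' @param study a `qeeg_study`.
#' @param out_dir output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(study, out_dir) {
  stopifnot(inherits(study, "qeeg_study"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(study$features, "features.csv")
  wr(study$subgroups, "subgroups.csv")
  wr(study$pooled, "pooled.csv")
  wr(study$heterogeneity, "heterogeneity.csv")
  wr(study$age_regression, "age_regression.csv")
  for (site in names(study$sensitivity)) {
    wr(study$sensitivity[[site]], sprintf("sensitivity_excl_%s.csv", site))
  }
  cfg_yaml <- yaml::as.yaml(serialize_config(study$config))
  manifest <- list(
    seed = study$config$seed,
    package = "qeegmeta",
    version = as.character(utils::packageVersion("qeegmeta")),
    config_checksum = derive_seed(0, cfg_yaml),
    tables = basename(paths)
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mpath))
}

# plain-list view of a config for YAML serialization
serialize_config <- function(config) {
  cfg <- unclass(config)
  if (inherits(cfg$cohort, "cohort_spec")) {
    sp <- unclass(cfg$cohort)
    sp$baseline <- lapply(sp$baseline, unclass)
    sp$effect <- unclass(sp$effect)
    sp$effect$gains <- as.list(sp$effect$gains)
    sp$effect$coupling_delta <- as.list(sp$effect$coupling_delta)
    sp$subgroups <- as.list(sp$subgroups)
    cfg$cohort <- sp
  }
  cfg
}

#' Read a study configuration from YAML
#'
#' Re-hydrates a [study_config()] (and an embedded [cohort_spec()]) from a
#' YAML file with the same keys the writer emits. Only simulate-mode fields
#' and scalar statistics settings are interpreted; anything absent falls
#' back to the defaults.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- default_cohort_spec()
  if (!is.null(y$cohort)) {
    cs <- y$cohort
    if (!is.null(cs$subgroups)) {
      cohort$subgroups <- as.data.frame(cs$subgroups, stringsAsFactors = FALSE)
    }
    if (!is.null(cs$effect)) {
      eff <- cs$effect
      cohort$effect <- delirium_effect_profile(
        peak_shift_hz = eff$peak_shift_hz %||% 1.5,
        delta_gain = eff$gains$delta %||% 1.9,
        theta_gain = eff$gains$theta %||% 1.25,
        alpha_gain = eff$gains$alpha %||% 0.85,
        beta_gain = eff$gains$beta %||% 0.55,
        coupling_delta = unlist(eff$coupling_delta %||%
                                  list(delta = 0.02, theta = 0.03,
                                       alpha = -0.03, beta = -0.08))
      )
    }
    for (f in c("epoch_len", "fs")) if (!is.null(cs[[f]])) cohort[[f]] <- cs[[f]]
    if (!is.null(cs$channels)) cohort$channels <- cs$channels
  }
  study_config(
    mode = y$mode %||% "simulate",
    cohort = cohort,
    edf_dir = y$edf_dir, cohort_csv = y$cohort_csv,
    exclude_channels = y$exclude_channels %||% c("A1", "A2", "Fp1", "Fp2"),
    n_boot = y$n_boot %||% 1000,
    conf_level = y$conf_level %||% 0.95,
    edge_trim_s = y$edge_trim_s %||% 0.5,
    leave_site_out = y$leave_site_out %||% "C",
    seed = y$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
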