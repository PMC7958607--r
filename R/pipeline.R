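# End-to-end orchestration: truncate -> log-transform -> non-wear detection
# -> validity filter -> cosine fits -> localized metrics -> clustering ->
# association, with flat CSV/JSON artifacts, an attrition log, and a
# checksum manifest so a rerun with the same config and seed is
# byte-identical.

#' Build a pipeline configuration
#'
#' Either `simulate` (a [sim_config()]) or `input` (paths to an epoch CSV
#' and a participant CSV) must be supplied. The resolved configuration is
#' serialized to the output directory as JSON for provenance.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; per-stage seeds derive from it.
#' @param simulate optional [sim_config()]; its seed is overridden by `seed`.
#' @param input optional list with `epoch_csv` and `participants_csv`.
#' @param epoch_seconds epoch width of the input data (default 60).
#' @param truncate_days midnight-truncation window (default 5).
#' @param choi list: `window_min`, `allowance_min`, `stream_min`.
#' @param valid_day_minutes valid-day wear threshold (default 600).
#' @param min_valid_days participant eligibility threshold (default 3).
#' @param bin_hours localized-metric bin width (default 4).
#' @param rise_aligned also emit rise-time-aligned localized metrics.
#' @param clustering list: `k`, `n_restarts`, `log_beta`.
#' @param assoc list: `tau`, `bootstrap_B`, `covariates`.
#' @param pfs list: `max_missing`, `cutpoint`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL, input = NULL,
                            epoch_seconds = 60L, truncate_days = 5L,
                            choi = list(window_min = 90, allowance_min = 2,
                                        stream_min = 30),
                            valid_day_minutes = 600L, min_valid_days = 3L,
                            bin_hours = 4, rise_aligned = FALSE,
                            clustering = list(k = 4L, n_restarts = 100L,
                                              log_beta = FALSE),
                            assoc = list(tau = 0.5, bootstrap_B = 200L,
                                         covariates = c("age", "sex", "race",
                                                        "bmi", "cesd")),
                            pfs = list(max_missing = 3L, cutpoint = 15L)) {
  if (is.null(simulate) && is.null(input))
    stop_rar("either a simulate block or input paths are required",
             "rar_config_error")
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_config"))
    simulate$seed <- as.integer(seed)
    epoch_seconds <- simulate$epoch_seconds
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         input = input, epoch_seconds = as.integer(epoch_seconds),
         truncate_days = truncate_days, choi = choi,
         valid_day_minutes = valid_day_minutes,
         min_valid_days = min_valid_days, bin_hours = bin_hours,
         rise_aligned = rise_aligned, clustering = clustering,
         assoc = assoc, pfs = pfs),
    class = "pipeline_config"
  )
}

PIPELINE_STAGES <- c("simulate", "clean", "fit", "localized", "cluster",
                     "associate")

#' Run the analysis pipeline
#'
#' Executes the stages in order up to `through`, writing one flat artifact
#' per stage plus an attrition log (participant counts in/out at every
#' filter) and a manifest of MD5 checksums. Later stages refuse to run
#' when an earlier stage they depend on is not included.
#'
#' @param config a [pipeline_config()].
#' @param through last stage to run (default `"associate"` = all).
#' @return invisibly, the manifest: data frame of artifact paths and MD5s.
#' @export
run_pipeline <- function(config, through = "associate") {
  stopifnot(inherits(config, "pipeline_config"))
  through <- match.arg(through, PIPELINE_STAGES)
  n_stage <- match(through, PIPELINE_STAGES)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "attrition.log")
  cat("", file = log_path)
  logline <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }

  # -- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    series <- cohort$series
    participants <- cohort$participants
    epochs_csv <- file.path(out, "epochs.csv")
    for (i in seq_along(series))
      write_epoch_csv(series[[i]], epochs_csv, append = i > 1L)
    utils::write.csv(participants, file.path(out, "participants.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(format_num_df(cohort$truth),
                     file.path(out, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    series <- read_epoch_csv(config$input$epoch_csv, config$epoch_seconds)
    participants <- utils::read.csv(config$input$participants_csv,
                                    stringsAsFactors = FALSE,
                                    colClasses = c(participant_id =
                                                     "character"))
  }
  logline("input: %d participants with epoch data", length(series))
  write_config_json(config, file.path(out, "config.json"))
  if (n_stage < match("clean", PIPELINE_STAGES))
    return(invisible(write_manifest(out)))

  # -- clean: truncate, log-transform, non-wear, validity ---------------
  series <- lapply(series, truncate_to_midnights, config$truncate_days)
  series <- lapply(series, log_transform)
  series <- lapply(series, function(s) {
    detect_nonwear_choi(s, config$choi$window_min, config$choi$allowance_min,
                        config$choi$stream_min)
  })
  summaries <- lapply(series, daily_wear_summary,
                      min_wear_minutes = config$valid_day_minutes,
                      min_valid_days = config$min_valid_days)
  wear_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(participant_id = s$participant_id, s$days)
  }))
  rownames(wear_df) <- NULL
  utils::write.csv(format_num_df(wear_df), file.path(out, "wear_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  eligible <- filter_valid_participants(summaries, config$min_valid_days)
  logline("clean: %d of %d participants eligible (>= %d valid days)",
          length(eligible), length(series), config$min_valid_days)
  series <- series[eligible]
  if (n_stage < match("fit", PIPELINE_STAGES))
    return(invisible(write_manifest(out)))

  # -- fit --------------------------------------------------------------
  fits <- lapply(series, fit_extended_cosine)
  fit_table <- rar_parameter_table(fits)
  utils::write.csv(format_num_df(fit_table),
                   file.path(out, "rar_parameters.csv"),
                   row.names = FALSE, quote = FALSE)
  logline("fit: %d fits, %d converged", nrow(fit_table),
          sum(fit_table$converged))
  if (n_stage < match("localized", PIPELINE_STAGES))
    return(invisible(write_manifest(out)))

  # -- localized metrics (valid days only) ------------------------------
  loc <- do.call(rbind, lapply(names(series), function(id) {
    sm <- summaries[[id]]
    lm_ <- localized_metrics(series[[id]], config$bin_hours,
                             valid_dates = sm$days$date[sm$days$valid_day])
    data.frame(participant_id = id, as.data.frame(lm_))
  }))
  utils::write.csv(format_num_df(loc),
                   file.path(out, "localized_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  if (config$rise_aligned) {
    loc_al <- do.call(rbind, lapply(names(series), function(id) {
      f <- fits[[id]]
      if (!isTRUE(f$converged)) return(NULL)
      sm <- summaries[[id]]
      al <- align_to_rise_time(series[[id]], f)
      lm_ <- localized_metrics(al, config$bin_hours)
      data.frame(participant_id = id, as.data.frame(lm_))
    }))
    utils::write.csv(format_num_df(loc_al),
                     file.path(out, "localized_metrics_rise_aligned.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (n_stage < match("cluster", PIPELINE_STAGES))
    return(invisible(write_manifest(out)))

  # -- cluster ----------------------------------------------------------
  feats <- build_feature_matrix(fit_table,
                                log_beta = isTRUE(config$clustering$log_beta))
  z <- standardize_features(feats)
  model <- kmeans_fit(z, config$clustering$k, config$clustering$n_restarts,
                      seed = derive_seed(config$seed, "cluster"))
  model <- label_clusters(model)
  diag <- cluster_diagnostics(z, seed = derive_seed(config$seed, "cluster"))
  clusters <- data.frame(
    participant_id = names(model$assignments),
    cluster_id = unname(model$assignments),
    label = if (!is.null(model$labels)) model$labels[model$assignments]
            else NA_character_
  )
  utils::write.csv(clusters, file.path(out, "clusters.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(within_ss = diag$within_ss,
         pca_variance = diag$pca_cum_variance,
         ward_heights = diag$ward_heights),
    file.path(out, "cluster_diagnostics.json"), digits = 10)
  logline("cluster: k=%d on %d participants, within_ss=%.4f",
          model$k, nrow(clusters), model$within_ss)
  if (n_stage < match("associate", PIPELINE_STAGES))
    return(invisible(write_manifest(out)))

  # -- associate --------------------------------------------------------
  assoc <- run_associations(fit_table, loc, clusters, participants, config)
  jsonlite::write_json(assoc, file.path(out, "associations.json"),
                       digits = 10, auto_unbox = TRUE, na = "null")
  logline("associate: %d participants in regression models", assoc$n)
  invisible(write_manifest(out))
}

# Deterministic numeric formatting so CSV checksums are reproducible.
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]) && is.null(attr(df[[j]], "class")))
      df[[j]] <- signif(df[[j]], 12)
  }
  df
}

write_config_json <- function(config, path) {
  cfg <- config
  cfg$out_dir <- NULL   # location is not analysis state; keep reruns
                        # in different directories byte-identical
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  jsonlite::write_json(unclass(cfg), path, digits = 10, auto_unbox = TRUE,
                       null = "null", na = "null")
}

write_manifest <- function(out) {
  files <- setdiff(list.files(out), "manifest.json")
  manifest <- data.frame(
    artifact = files,
    md5 = unname(tools::md5sum(file.path(out, files)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"))
  manifest
}

# Association battery mirroring the published analyses: per-parameter
# median regressions with covariate adjustment, per-bin mean/SD regressions,
# cluster-profile regression with LRT against the covariate-only model, and
# rank tests of PFS across profiles.
run_associations <- function(fit_table, loc, clusters, participants, config) {
  cov_names <- config$assoc$covariates
  tau <- config$assoc$tau
  B <- config$assoc$bootstrap_B
  seed <- derive_seed(config$seed, "assoc")

  pts <- participants
  if (!"pfs_score" %in% names(pts)) {
    item_cols <- grep("^pfs_[0-9]+$", names(pts), value = TRUE)
    pts$pfs_score <- apply(pts[item_cols], 1L, function(it)
      score_pfs(as.numeric(it), config$pfs$max_missing)$score)
  }
  pts$fatigued <- classify_fatigability(pts$pfs_score, config$pfs$cutpoint)
  df <- merge(fit_table, pts, by = "participant_id")
  covars <- df[, cov_names, drop = FALSE]

  param_models <- lapply(
    c("alpha", "beta", "phi", "amp", "mesor_log", "up_mesor", "down_mesor",
      "pseudo_f"),
    function(p) {
      fit <- median_regression(df$pfs_score,
                               cbind(df[, p, drop = FALSE], covars),
                               tau = tau, bootstrap_B = B, seed = seed)
      list(parameter = p, coefficients = fit$coefficients, n = fit$n)
    })

  dfc <- merge(df, clusters, by = "participant_id")
  dfc$label <- factor(dfc$label,
                      levels = intersect(
                        c("Earlier Risers", "More Active/Robust", "Later RAR",
                          "Less Active/Robust"), unique(dfc$label)))
  cluster_fit <- median_regression(
    dfc$pfs_score, cbind(dfc[, "label", drop = FALSE],
                         dfc[, cov_names, drop = FALSE]),
    tau = tau, bootstrap_B = B, seed = seed)
  reduced_fit <- median_regression(
    dfc$pfs_score, dfc[, cov_names, drop = FALSE],
    tau = tau, bootstrap_B = B, seed = seed)
  lrt <- qr_likelihood_ratio_test(cluster_fit, reduced_fit)
  rank_tests <- group_comparison_tests(dfc$pfs_score, dfc$label)

  list(
    n = nrow(df),
    parameter_models = param_models,
    cluster_model = list(coefficients = cluster_fit$coefficients,
                         n = cluster_fit$n),
    lrt = lrt[c("statistic", "df", "p_value")],
    kruskal = rank_tests$kruskal,
    pairwise_wilcoxon = rank_tests$pairwise
  )
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `clean`, `fit`, `localized`, `cluster`,
#' `associate` (each runs the pipeline through that stage) and `run-all`.
#' Flags: `--seed <int>`, `--out <dir>`, `--n <participants>`. The CLI
#' always runs in simulate mode; programmatic use of [pipeline_config()]
#' supports external epoch/participant CSVs.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status 0, invisibly.
#' @export
rar_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: rar-pipeline <simulate|clean|fit|localized|cluster|",
        "associate|run-all> [--seed N] [--out DIR] [--n N]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out <- opt("--out", "rar-output")
  n <- as.integer(opt("--n", "20"))
  cfg <- pipeline_config(out_dir = out, seed = seed,
                         simulate = sim_config(n_participants = n,
                                               nonwear_rate = 0.5,
                                               seed = seed))
  through <- if (cmd == "run-all") "associate" else cmd
  if (!through %in% PIPELINE_STAGES)
    stop_rar(sprintf("unknown subcommand '%s'", cmd), "rar_usage_error")
  run_pipeline(cfg, through = through)
  invisible(0L)
}
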