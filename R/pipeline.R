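#' Read a run configuration
#'
#' A declarative YAML file fully specifies a run together with the data and
#' the seed. Recognized keys: `sessions` (list of `label`, `traps`,
#' `encounters`, optional `truth`), `sharing` (one group id per session),
#' `occasion_length` (default 5 trap days), `buffer` (default 15000 m),
#' `resolution` (default 1500 m), `estimators` (subset of
#' `scr, m0, mh, mmdm`), `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  defaults <- list(occasion_length = 5, buffer = 15000, resolution = 1500,
                   estimators = c("scr", "m0", "mh", "mmdm"), seed = 1L,
                   out_dir = NULL, sharing = NULL)
  config <- utils::modifyList(defaults, config)
  known <- c("scr", "m0", "mh", "mmdm")
  bad <- setdiff(config$estimators, known)
  if (length(bad))
    abort_validation(sprintf("unknown estimator '%s' (known: %s)",
                             bad[1], paste(known, collapse = ", ")),
                     "scrdens_config_error")
  if (is.null(config$sessions) || !length(config$sessions))
    abort_validation("config needs at least one session", "scrdens_config_error")
  for (s in config$sessions) {
    for (f in c("traps", "encounters")) {
      if (is.null(s[[f]]) || !file.exists(s[[f]]))
        abort_validation(sprintf("session file not found: %s", s[[f]] %||% paste0("<missing ", f, ">")),
                         "scrdens_config_error")
    }
  }
  if (!is.null(config$sharing) && length(config$sharing) != length(config$sessions))
    abort_validation("sharing must have one entry per session", "scrdens_config_error")
  structure(config, class = c("run_config", "list"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    # validation problems keep their own class; everything else is tagged
    # with the stage at which it happened
    if (inherits(e, "scrdens_validation_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          "scrdens_stage_error")
  })
}

#' Run the full density-estimation pipeline
#'
#' Reads the configured sessions, fits the SCR model (with parameter
#' sharing), the nonspatial M0 and Chao-Mh estimators and the MMDM/HMMDM
#' effective-trapping-area conversions, and writes a per-session summary CSV
#' (the column structure of a spatial-vs-nonspatial comparison table),
#' density rasters (ESRI ASCII + long CSV) and a machine-readable JSON run
#' log with versions, seed and convergence diagnostics. Deterministic given
#' the seed. Any stage failure aborts with a stage-named error.
#'
#' @param config a config list, `run_config`, or path to a YAML file
#'   ([read_run_config()]).
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with `summary` (data frame), `fit` (the
#'   `scr_fit` if run), `log`, and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- stage("config", validate_run_config(unclass(config)))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort_validation("no output directory given",
                                         "scrdens_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  sessions <- stage("read", {
    lapply(config$sessions, function(s) {
      traps <- read_traps(s$traps, occasion_length = config$occasion_length)
      list(traps = traps,
           encounters = read_encounters(s$encounters, traps,
                                        occasion_length = config$occasion_length,
                                        session = s$label %||% NULL),
           truth = if (!is.null(s$truth)) jsonlite::read_json(s$truth, simplifyVector = TRUE))
    })
  })
  labels <- vapply(seq_along(sessions),
                   function(i) config$sessions[[i]]$label %||%
                     sessions[[i]]$encounters$session_id, character(1))
  S <- length(sessions)
  summary_df <- data.frame(
    session = labels,
    n_individuals = vapply(sessions, function(s) dim(s$encounters$y)[1], numeric(1)),
    n_detections = vapply(sessions, function(s) sum(s$encounters$y), numeric(1)))
  log <- list(package = "scrdens",
              version = as.character(utils::packageVersion("scrdens")),
              r_version = R.version.string,
              seed = config$seed, estimators = config$estimators,
              sessions = labels, complete = FALSE)
  fit <- NULL
  paths <- character(0)
  if ("scr" %in% config$estimators) {
    fit <- stage("scr", fit_scr(session_set(sessions, config$sharing),
                                buffer = config$buffer,
                                resolution = config$resolution))
    grp <- as.integer(fit$sharing)
    summary_df$scr_N <- fit$per_session$N
    summary_df$scr_N_se <- fit$per_session$se_N
    summary_df$scr_D_100km2 <- fit$per_session$D_per_100km2
    summary_df$scr_D_se <- fit$per_session$se_D
    summary_df$p0_logit <- fit$params$p0_logit[grp]
    summary_df$p0_logit_se <- fit$se$p0_logit[grp]
    summary_df$log_sigma <- fit$params$log_sigma[grp]
    summary_df$log_sigma_se <- fit$se$log_sigma[grp]
    log$scr <- list(converged = fit$converged, grad_norm = fit$grad_norm,
                    loglik = fit$logLik)
    for (s in seq_len(S)) {
      surf <- density_surface(fit, s)
      p_asc <- file.path(out_dir, sprintf("density_%s.asc", labels[s]))
      p_csv <- file.path(out_dir, sprintf("density_%s.csv", labels[s]))
      stage("report", { write_density_asc(surf, p_asc); write_density_csv(surf, p_csv) })
      paths <- c(paths, p_asc, p_csv)
    }
  }
  if (any(c("m0", "mh") %in% config$estimators)) {
    freqs <- stage("nonspatial", lapply(sessions, function(s)
      capture_frequencies(s$encounters)))
    if ("m0" %in% config$estimators) {
      m0 <- stage("nonspatial", lapply(freqs, fit_m0))
      summary_df$m0_N <- vapply(m0, function(f) f$N, numeric(1))
      summary_df$m0_N_se <- vapply(m0, function(f) f$se_N, numeric(1))
    }
    if ("mh" %in% config$estimators) {
      mh <- stage("nonspatial", lapply(freqs, fit_mh_chao))
      summary_df$mh_N <- vapply(mh, function(f) f$N, numeric(1))
      summary_df$mh_N_se <- vapply(mh, function(f) f$se_N, numeric(1))
    }
  }
  if ("mmdm" %in% config$estimators) {
    stage("mmdm", for (s in seq_len(S)) {
      em <- try(eta_from_mmdm(sessions[[s]]$encounters, sessions[[s]]$traps), silent = TRUE)
      if (inherits(em, "try-error")) {
        summary_df[s, c("mmdm_m", "eta_mmdm_km2", "eta_hmmdm_km2")] <- NA_real_
        next
      }
      eh <- eta_from_mmdm(sessions[[s]]$encounters, sessions[[s]]$traps, half = TRUE)
      summary_df[s, "mmdm_m"] <- em$mmdm
      summary_df[s, "eta_mmdm_km2"] <- em$eta_area / 1e6
      summary_df[s, "eta_hmmdm_km2"] <- eh$eta_area / 1e6
      for (est in intersect(c("m0", "mh"), config$estimators)) {
        N <- summary_df[s, paste0(est, "_N")]
        seN <- summary_df[s, paste0(est, "_N_se")]
        dm <- nonspatial_density(N, seN, em)
        dh <- nonspatial_density(N, seN, eh)
        summary_df[s, paste0(est, "_D_mmdm")] <- dm$density
        summary_df[s, paste0(est, "_D_mmdm_se")] <- dm$se
        summary_df[s, paste0(est, "_D_hmmdm")] <- dh$density
        summary_df[s, paste0(est, "_D_hmmdm_se")] <- dh$se
      }
    })
  }
  # truth-recovery diagnostics for synthetic sessions carrying a truth sidecar
  truths <- which(!vapply(sessions, function(s) is.null(s$truth), logical(1)))
  if (length(truths)) {
    log$recovery <- lapply(truths, function(s) {
      tr <- sessions[[s]]$truth
      rec <- list(session = labels[s], N_true = tr$N_true,
                  p0_true = tr$p0_true, sigma_true = tr$sigma_true)
      if (!is.null(fit)) {
        rec$N_hat <- fit$per_session$N[s]
        rec$p0_hat <- stats::plogis(fit$params$p0_logit[as.integer(fit$sharing)[s]])
        rec$sigma_hat <- exp(fit$params$log_sigma[as.integer(fit$sharing)[s]])
      }
      rec
    })
  }
  p_sum <- file.path(out_dir, "summary.csv")
  p_log <- file.path(out_dir, "run_log.json")
  stage("report", {
    utils::write.csv(format(summary_df, digits = 10, trim = TRUE, scientific = FALSE),
                     p_sum, row.names = FALSE, quote = FALSE)
    log$complete <- TRUE
    jsonlite::write_json(log, p_log, auto_unbox = TRUE, digits = NA)
  })
  invisible(list(summary = summary_df, fit = fit, log = log,
                 paths = c(paths, summary = p_sum, log = p_log)))
}

#' Read a survey summary table
#'
#' A transcription of per-survey bookkeeping for a multi-session camera-trap
#' programme: survey label, number of camera traps (two per site), mean trap
#' days, occasions, detections, detected individuals and sex tallies. A copy
#' for the lynx monitoring programme in the French Jura mountains ships in
#' `inst/extdata/jura_surveys.csv`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_survey_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Tally a survey summary table
#'
#' Programme-level bookkeeping totals: detected individuals, detection
#' events, and trap days. Trap days come from per-area totals when supplied
#' (`trap_day_totals`, a data frame with columns `area` and `trap_days`), and
#' a per-survey reconstruction `sites x mean trap days` (with
#' `sites = n_camera_traps / 2`, two cameras per site) is returned alongside
#' as a cross-check.
#'
#' @param surveys data frame from [read_survey_table()].
#' @param trap_day_totals optional data frame of per-area trap-day totals.
#' @return list with `n_individuals`, `n_detections`, `site_trap_days`
#'   (reconstructed) and, when totals are given, `trap_days`.
#' @export
tally_surveys <- function(surveys, trap_day_totals = NULL) {
  out <- list(
    n_individuals = sum(surveys$n_individuals),
    n_detections = sum(surveys$n_detections),
    site_trap_days = sum(surveys$n_camera_traps / 2 * surveys$mean_trap_days))
  if (!is.null(trap_day_totals))
    out$trap_days <- sum(trap_day_totals$trap_days)
  out
}
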