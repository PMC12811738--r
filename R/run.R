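# Pipeline orchestration: simulate -> process -> fit, each stage reading and
# writing plain-text files so runs are resumable and auditable. A thin
# command-line front-end lives in inst/cli/sighstress.R.

#' Simulate and process a cohort in memory
#'
#' Streams subjects one at a time through [simulate_participant()] and
#' [process_recording()], keeping only the per-task summary rows (and,
#' optionally, the per-subject RRI/SBP spectra), so cohort size is not bound
#' by memory.
#'
#' @inheritParams simulate_cohort
#' @param keep_spectra If `TRUE`, per-subject Welch spectra are collected per
#'   task (`spectra[[task]]$rri` / `$sbp`, lists over subjects).
#' @return List: `summary` (long table via [build_long_table()]), `truth`
#'   (cohort ground-truth table), and `spectra` when requested.
#' @export
simulate_process_cohort <- function(n, fraction_female = 0.65, seed = 1,
                                    fs = 250, timeline = build_protocol(),
                                    dispersions = cohort_dispersions(),
                                    insert_calibration_gaps = FALSE,
                                    keep_spectra = FALSE) {
  drawn <- draw_cohort_params(n, fraction_female, dispersions, seed)
  ids <- sprintf("S%03d", seq_len(n))
  rows <- vector("list", n)
  spectra <- NULL
  if (keep_spectra) {
    spectra <- stats::setNames(
      rep(list(list(rri = list(), sbp = list())),
          nrow(timeline$segments)), timeline$segments$label)
  }
  for (i in seq_len(n)) {
    rec <- simulate_participant(drawn$params[[i]], timeline,
                                seed = drawn$seeds[i], fs = fs,
                                insert_calibration_gaps = insert_calibration_gaps)
    pr <- process_recording(rec, subject = ids[i])
    rows[[i]] <- pr$summary
    if (keep_spectra) {
      for (lab in names(spectra)) {
        spectra[[lab]]$rri[[ids[i]]] <- pr$spectra[[lab]]$rri
        spectra[[lab]]$sbp[[ids[i]]] <- pr$spectra[[lab]]$sbp
      }
    }
  }
  truth <- data.frame(
    subject = ids, sex = drawn$sex, seed = drawn$seeds,
    mean_rri = vapply(drawn$params, `[[`, numeric(1), "mean_rri"),
    rsa_delay = vapply(drawn$params, `[[`, numeric(1), "rsa_delay"),
    arm_length = vapply(drawn$params, `[[`, numeric(1), "arm_length"),
    stringsAsFactors = FALSE)
  out <- list(summary = build_long_table(do.call(rbind, rows)), truth = truth)
  if (keep_spectra) out$spectra <- spectra
  out
}

#' Simulate a cohort to disk
#'
#' Draws per-subject parameters, simulates each recording, and writes one
#' directory per subject plus a cohort ground-truth table and a manifest
#' carrying the configuration hash.
#'
#' @param config A [default_config()]-shaped configuration.
#' @param out_dir Output directory.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_data("cannot create output directory: ", out_dir)
  timeline <- do.call(build_protocol, config$protocol)
  drawn <- draw_cohort_params(config$n_subjects, config$fraction_female,
                              seed = config$seed)
  ids <- sprintf("S%03d", seq_len(config$n_subjects))
  truth_rows <- vector("list", config$n_subjects)
  for (i in seq_along(ids)) {
    rec <- simulate_participant(
      drawn$params[[i]], timeline, seed = drawn$seeds[i], fs = config$fs,
      insert_calibration_gaps = isTRUE(config$insert_calibration_gaps))
    write_recording(rec, file.path(out_dir, ids[i]))
    gt <- rec$ground_truth$beats
    truth_rows[[i]] <- data.frame(
      subject = ids[i], sex = drawn$sex[i], seed = drawn$seeds[i],
      mean_rri = drawn$params[[i]]$mean_rri,
      rsa_delay = drawn$params[[i]]$rsa_delay,
      arm_length = drawn$params[[i]]$arm_length,
      n_beats = nrow(gt), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  data.table::fwrite(truth, file.path(out_dir, "cohort_truth.csv"))
  manifest <- list(config = unclass(config), config_hash = config_hash(config),
                   subjects = ids)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Process simulated or recorded subjects on disk
#'
#' Runs [process_recording()] on every subject directory under `in_dir`,
#' writing per-subject beat and breath tables and the cohort-level long task
#' summary. Subjects whose files are missing or unreadable are skipped with a
#' logged reason.
#'
#' @param in_dir Directory produced by [run_simulate()] (or hand-assembled
#'   with the same layout).
#' @param out_dir Output directory.
#' @param config Configuration (low-pass cutoff, resampling rate).
#' @return List with the long `summary` table and the `log` data.frame,
#'   invisibly.
#' @export
run_process <- function(in_dir, out_dir, config = default_config()) {
  if (!dir.exists(in_dir)) stop_data("input directory not found: ", in_dir)
  subj_dirs <- list.dirs(in_dir, recursive = FALSE)
  if (!length(subj_dirs)) stop_data("no subject directories under ", in_dir)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_data("cannot create output directory: ", out_dir)
  hash <- config_hash(config)
  rows <- list(); logs <- list()
  for (sd in subj_dirs) {
    id <- basename(sd)
    res <- tryCatch({
      rec <- read_recording(sd)
      pr <- process_recording(rec, subject = id,
                              lowpass_hz = config$lowpass_hz,
                              resample_rate = config$resample_rate)
      out_sd <- file.path(out_dir, id)
      dir.create(out_sd, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(pr$beat_table, file.path(out_sd, "beats.csv"))
      data.table::fwrite(pr$breaths, file.path(out_sd, "breaths.csv"))
      pr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logs[[id]] <- data.frame(subject = id, status = "skipped",
                               reason = conditionMessage(res),
                               n_beats = NA, n_corrected = NA,
                               n_in_calibration = NA, stringsAsFactors = FALSE)
    } else {
      rows[[id]] <- res$summary
      logs[[id]] <- data.frame(subject = id, status = "ok", reason = "",
                               n_beats = res$log$n_beats,
                               n_corrected = res$log$n_corrected,
                               n_in_calibration = res$log$n_in_calibration,
                               stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  log <- do.call(rbind, logs)
  if (!is.null(summary)) {
    summary$config_hash <- hash
    data.table::fwrite(summary, file.path(out_dir, "task_summary.csv"))
  }
  data.table::fwrite(log, file.path(out_dir, "processing_log.csv"))
  invisible(list(summary = summary, log = log))
}

#' Fit the seven-outcome dissection from a task summary file
#'
#' @param summary_csv Path to the long task summary written by
#'   [run_process()].
#' @param out_dir Output directory for model CSVs and the direction report.
#' @param config Configuration (MAP covariate variant, alpha).
#' @return The [dissect_all_outcomes()] result, invisibly.
#' @export
run_fit <- function(summary_csv, out_dir, config = default_config()) {
  if (!file.exists(summary_csv)) stop_data("summary file not found: ", summary_csv)
  tab <- as.data.frame(data.table::fread(summary_csv))
  need <- c("subject", "sex", "task")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_data("malformed summary CSV, missing column(s): ",
              paste(miss, collapse = ", "))
  long <- build_long_table(tab)
  dis <- dissect_all_outcomes(long,
                              map_covariates = config$model$map_covariates,
                              alpha = config$model$alpha)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_data("cannot create output directory: ", out_dir)
  fe <- do.call(rbind, lapply(names(dis$fits), function(oc) {
    cf <- summary(dis$fits[[oc]]$fit)$coefficients
    data.frame(outcome = oc, term = rownames(cf), estimate = cf[, "Estimate"],
               se = cf[, "Std. Error"], df = cf[, "df"], t = cf[, "t value"],
               p = cf[, "Pr(>|t|)"],
               covariates = paste(dis$fits[[oc]]$covariates, collapse = "+"),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  data.table::fwrite(fe, file.path(out_dir, "fixed_effects.csv"))
  data.table::fwrite(dis$task_contrasts, file.path(out_dir, "task_contrasts.csv"))
  data.table::fwrite(dis$sex_contrasts, file.path(out_dir, "sex_contrasts.csv"))
  infl <- do.call(rbind, lapply(names(dis$influence), function(oc)
    cbind(outcome = oc, dis$influence[[oc]])))
  if (!is.null(infl))
    data.table::fwrite(infl, file.path(out_dir, "influence.csv"))
  data.table::fwrite(dis$summary, file.path(out_dir, "direction_summary.csv"))
  md <- c("# Task and sex effect directions", "",
          paste0("Configuration hash: ", config_hash(config)), "",
          "| Outcome | Task pattern | Sex | Task x sex |",
          "|---|---|---|---|",
          sprintf("| %s | %s | %s | %s |", dis$summary$outcome,
                  dis$summary$task_pattern, dis$summary$sex_effect,
                  dis$summary$interaction))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(dis)
}
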