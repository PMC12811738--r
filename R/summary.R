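# Per-task outcome rows: one participant x task row carrying the seven
# modelled outcomes (HR, ln LF/HF-HRV, PTTv, MAP, ln LF/HF-BPV) plus the
# covariates RSA and PWV.

#' Summarize one task segment into an outcome row
#'
#' @param beat_table Beat table restricted to the task segment (artifact
#'   corrected, calibration flagged).
#' @param rsa_events data.frame from [compute_rsa_events()] for the segment.
#' @param spectra List with elements `rri` and `sbp`, each a [welch_psd()] or
#'   `NULL` when not computable.
#' @param task Task label.
#' @param subject Subject id.
#' @param sex `"M"` or `"F"`.
#' @param arm_length Arm length, m, for pulse wave velocity.
#' @return One-row data.frame: `subject`, `sex`, `task`, `hr` (bpm),
#'   `ln_lf_hrv`, `ln_hf_hrv` (ln ms^2), `pttv` (ms), `map` (mmHg),
#'   `ln_lf_bpv`, `ln_hf_bpv` (ln mmHg^2), `rsa` (s), `pwv` (m/s). Undefined
#'   components are `NA`; the row is always emitted.
#' @export
summarize_task <- function(beat_table, rsa_events, spectra, task,
                           subject = "S001", sex = "F", arm_length = 0.65) {
  rri_ok <- beat_table$rri[!is.na(beat_table$rri) & !beat_table$excluded]
  hr <- if (length(rri_ok)) 60000 / mean(rri_ok) else NA_real_

  bp_valid <- !beat_table$in_calibration & !beat_table$excluded
  ptt_ok <- beat_table$ptt[bp_valid & !is.na(beat_table$ptt)]
  pttv <- if (length(ptt_ok) >= 2L) stats::sd(ptt_ok) else NA_real_
  pwv <- if (length(ptt_ok)) compute_pwv(arm_length, mean(ptt_ok)) else NA_real_

  map_ok <- beat_table$map[bp_valid & !is.na(beat_table$map)]
  map <- if (length(map_ok)) mean(map_ok) else NA_real_

  rsa <- if (!is.null(rsa_events) && any(!is.na(rsa_events$rsa_delay))) {
    mean(rsa_events$rsa_delay, na.rm = TRUE)
  } else NA_real_

  lnband <- function(spec, b) {
    if (is.null(spec)) return(NA_real_)
    suppressWarnings(band_power(spec, b)$ln_power)
  }
  data.frame(subject = subject, sex = sex, task = task,
             hr = hr,
             ln_lf_hrv = lnband(spectra$rri, "LF"),
             ln_hf_hrv = lnband(spectra$rri, "HF"),
             pttv = pttv, map = map,
             ln_lf_bpv = lnband(spectra$sbp, "LF"),
             ln_hf_bpv = lnband(spectra$sbp, "HF"),
             rsa = rsa, pwv = pwv,
             stringsAsFactors = FALSE)
}

#' Run the full beat-processing and spectral pipeline on one recording
#'
#' Filters the channels (10-Hz zero-phase low-pass), detects R peaks, systolic
#' pressure peaks and breath peaks, corrects RRI artifacts, applies the
#' calibration-gap exclusion, computes per-beat PTT and MAP, the RSA proxy per
#' eligible breath, Welch spectra of the 4-Hz resampled RRI and SBP series per
#' task, and one outcome row per task.
#'
#' @param rec A [simulate_participant()] recording, or any list with
#'   `channels$ecg/bp/resp`, `fs`, `calibration_gaps`, `timeline`, and
#'   (optionally) `params$arm_length`, `params$sex`.
#' @param subject Subject id attached to the summary rows.
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param resample_rate Uniform grid rate for spectra, Hz.
#' @return List of class `fivs_processed`: `beat_table`, `breaths` (with RSA
#'   delays on eligible events), `spectra` (per task: `rri`, `sbp`),
#'   `summary` (3-row data.frame), and `log` (counts).
#' @export
process_recording <- function(rec, subject = "S001", lowpass_hz = 10,
                              resample_rate = 4) {
  if (is.null(rec$channels)) stop_data("recording carries no channels")
  fs <- rec$fs
  timeline <- rec$timeline
  arm <- if (!is.null(rec$params)) rec$params$arm_length else 0.65
  sex <- if (!is.null(rec$params)) rec$params$sex else NA_character_

  ecg <- lowpass_filter(sampled_signal(rec$channels$ecg, fs), lowpass_hz)
  bp_raw <- sampled_signal(rec$channels$bp, fs)
  resp <- lowpass_filter(sampled_signal(rec$channels$resp, fs), lowpass_hz)

  r_times <- detect_r_peaks(ecg)
  if (length(r_times) < 4L) stop_data("too few beats detected")
  # PTT uses the *raw* pressure peak; the beat window excludes the R artifact
  bp_peaks <- detect_bp_peaks(bp_raw, r_times)
  bt <- build_beat_table(r_times, bp_peaks)
  bt <- correct_rri_artifacts(bt)
  n_corrected <- attr(bt, "n_corrected")
  bt <- compute_ptt_series(bt)
  bt <- apply_calibration_exclusion(bt, rec$calibration_gaps)
  bt$map <- extract_map_series(bp_raw, r_times, rec$calibration_gaps)
  bt$pwv <- ifelse(is.na(bt$ptt) | bt$in_calibration, NA_real_,
                   compute_pwv(arm, pmax(bt$ptt, 1e-6)))

  cues <- timeline$cues$time
  breaths <- detect_resp_peaks(resp, cues)

  rri_pk <- rri_signal_peaks(bt)
  tasks <- timeline$segments$label
  spectra <- list()
  rows <- vector("list", length(tasks))
  rsa_all <- list()
  for (k in seq_along(tasks)) {
    seg <- timeline$segments[k, ]
    in_seg <- bt$r_time >= seg$start & bt$r_time < seg$end
    btk <- bt[in_seg, , drop = FALSE]
    brk <- breaths[breaths$resp_peak_time >= seg$start &
                     breaths$resp_peak_time < seg$end, , drop = FALSE]
    breath_period <- 60 / 15
    if (nrow(brk) > 1L)
      breath_period <- stats::median(diff(brk$resp_peak_time))
    rsa_ev <- suppressWarnings(
      compute_rsa_events(brk, rri_pk, seg$label,
                         max_delay_s = max(breath_period, 2)))
    rsa_ev$task <- if (nrow(rsa_ev)) seg$label else character(0)
    rsa_all[[k]] <- rsa_ev

    sp <- list(rri = NULL, sbp = NULL)
    rr_ok <- !is.na(btk$rri)
    if (sum(rr_ok) >= 4L) {
      us <- resample_to_uniform(btk$rri[rr_ok], btk$r_time[rr_ok],
                                rate = resample_rate, source = "rri")
      sp$rri <- tryCatch(welch_psd(us), sighstress_data_error = function(e) NULL)
    }
    sb_ok <- !is.na(btk$sbp) & !btk$in_calibration & !btk$excluded &
      !is.na(btk$bp_peak_time)
    if (sum(sb_ok) >= 4L) {
      us <- resample_to_uniform(btk$sbp[sb_ok], btk$bp_peak_time[sb_ok],
                                rate = resample_rate, source = "sbp")
      sp$sbp <- tryCatch(welch_psd(us), sighstress_data_error = function(e) NULL)
    }
    spectra[[seg$label]] <- sp
    rows[[k]] <- summarize_task(btk, rsa_ev, sp, seg$label, subject, sex, arm)
  }

  structure(list(
    beat_table = bt,
    breaths = do.call(rbind, rsa_all),
    spectra = spectra,
    summary = do.call(rbind, rows),
    log = list(n_beats = nrow(bt), n_corrected = n_corrected,
               n_in_calibration = sum(bt$in_calibration),
               n_excluded = sum(bt$excluded))
  ), class = "fivs_processed")
}
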