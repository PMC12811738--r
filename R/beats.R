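# Beat-level index construction: the BeatTable is the pipeline's central
# ledger (one row per detected R peak).

#' R-to-R interval series from R-peak times
#'
#' @param r_times Strictly increasing R-peak times, s.
#' @return Numeric vector of RRIs in ms, one per *interval*
#'   (`length(r_times) - 1`); empty for fewer than two peaks.
#' @export
compute_rri_series <- function(r_times) {
  if (length(r_times) < 2L) return(numeric(0))
  if (is.unsorted(r_times, strictly = TRUE))
    stop_data("R-peak times must be strictly increasing")
  diff(r_times) * 1000
}

#' Assemble a beat table from detected events
#'
#' @param r_times R-peak times, s.
#' @param bp_peaks Optional data.frame from [detect_bp_peaks()] (same length).
#' @return data.frame with one row per beat: `r_time`, `rri` (ms, `NA` for the
#'   first beat), `bp_peak_time`, `sbp`, and flag columns
#'   `artifact_corrected`, `in_calibration`, `excluded`, `exclude_reason`.
#' @export
build_beat_table <- function(r_times, bp_peaks = NULL) {
  nb <- length(r_times)
  if (nb == 0L)
    return(data.frame(r_time = numeric(0), rri = numeric(0),
                      bp_peak_time = numeric(0), sbp = numeric(0),
                      artifact_corrected = logical(0),
                      in_calibration = logical(0), excluded = logical(0),
                      exclude_reason = character(0)))
  rri <- c(NA_real_, compute_rri_series(r_times))
  if (is.null(bp_peaks))
    bp_peaks <- data.frame(bp_peak_time = rep(NA_real_, nb),
                           sbp = rep(NA_real_, nb))
  stopifnot(nrow(bp_peaks) == nb)
  data.frame(r_time = r_times, rri = rri,
             bp_peak_time = bp_peaks$bp_peak_time, sbp = bp_peaks$sbp,
             artifact_corrected = FALSE, in_calibration = FALSE,
             excluded = FALSE, exclude_reason = NA_character_)
}

#' Automated RRI artifact correction
#'
#' Algorithmic stand-in for manual editing of ectopic beats and lost spikes:
#' an RRI is flagged when it falls outside absolute physiological bounds or
#' deviates from the 5-beat running median by more than `rel_tol`. Flagged
#' values are replaced by linear interpolation over the neighbouring clean
#' beats. A record with more than `max_flag_frac` of beats flagged is rejected
#' as unusable.
#'
#' @param beat_table A [build_beat_table()] data.frame.
#' @param abs_bounds Physiological RRI bounds, ms (default `c(300, 2000)`).
#' @param rel_tol Maximum relative deviation from the running median
#'   (default 0.3).
#' @param max_flag_frac Quality-failure threshold on the flagged fraction
#'   (default 0.2).
#' @return The beat table with corrected `rri` and `artifact_corrected` flags;
#'   attribute `n_corrected` carries the flag count.
#' @export
correct_rri_artifacts <- function(beat_table, abs_bounds = c(300, 2000),
                                  rel_tol = 0.3, max_flag_frac = 0.2) {
  rri <- beat_table$rri
  ok <- which(!is.na(rri))
  if (length(ok) < 3L) {
    attr(beat_table, "n_corrected") <- 0L
    return(beat_table)
  }
  v <- rri[ok]
  med <- stats::runmed(v, k = 5, endrule = "median")
  bad <- v < abs_bounds[1] | v > abs_bounds[2] | abs(v - med) > rel_tol * med
  if (mean(bad) > max_flag_frac)
    stop_quality(sprintf(
      "record rejected: %.0f%% of beats flagged as artifacts (limit %.0f%%)",
      100 * mean(bad), 100 * max_flag_frac))
  if (any(bad)) {
    good_idx <- which(!bad)
    if (length(good_idx) >= 2L) {
      v[bad] <- stats::approx(good_idx, v[good_idx], xout = which(bad),
                              rule = 2)$y
    }
    rri[ok] <- v
    beat_table$rri <- rri
    beat_table$artifact_corrected[ok[bad]] <- TRUE
  }
  attr(beat_table, "n_corrected") <- sum(bad)
  beat_table
}

#' Pulse transit time per beat
#'
#' PTT is the delay from each R peak to its subsequent systolic pressure peak,
#' in ms. In the PTT *time series*, each value is timestamped by its BP peak.
#' Beats with a negative PTT (detection inconsistency) are flagged invalid.
#'
#' @param beat_table A beat table carrying `r_time` and `bp_peak_time`.
#' @return The beat table with a `ptt` column (ms, `NA` when the BP peak is
#'   undefined) and invalid beats excluded.
#' @export
compute_ptt_series <- function(beat_table) {
  ptt <- (beat_table$bp_peak_time - beat_table$r_time) * 1000
  neg <- !is.na(ptt) & ptt < 0
  if (any(neg)) {
    beat_table$excluded[neg] <- TRUE
    beat_table$exclude_reason[neg] <- "negative ptt"
    ptt[neg] <- NA_real_
  }
  beat_table$ptt <- ptt
  beat_table
}

#' Flag beats inside pressure calibration gaps
#'
#' Beats whose BP peak falls inside any calibration interval are flagged
#' `in_calibration`; they are excluded from every pressure-derived summary
#' (PTT, PTTv, SBP spectra, MAP) while their RRI is retained. Overlapping
#' gaps are merged silently.
#'
#' @param beat_table A beat table with `bp_peak_time`.
#' @param calibration_gaps data.frame with `start`, `end` (s), possibly empty.
#' @return The beat table with updated `in_calibration` flags.
#' @export
apply_calibration_exclusion <- function(beat_table, calibration_gaps) {
  if (is.null(calibration_gaps) || nrow(calibration_gaps) == 0L)
    return(beat_table)
  g <- merge_intervals(calibration_gaps)
  hit <- in_any_gap(beat_table$bp_peak_time, g)
  hit[is.na(hit)] <- FALSE
  beat_table$in_calibration <- beat_table$in_calibration | hit
  beat_table
}

merge_intervals <- function(g) {
  g <- g[order(g$start), , drop = FALSE]
  out <- g[0, ]
  for (i in seq_len(nrow(g))) {
    if (nrow(out) && g$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], g$end[i])
    } else out <- rbind(out, g[i, ])
  }
  out
}

#' Pulse wave velocity from arm length and transit time
#'
#' @param arm_length Distance between pulse measurement sites, m.
#' @param ptt Pulse transit time, ms (vectorized).
#' @return Pulse wave velocity, m/s.
#' @examples
#' compute_pwv(0.6, 200)  # 3 m/s
#' @export
compute_pwv <- function(arm_length, ptt) {
  if (!is.finite(arm_length) || arm_length <= 0)
    stop_config("arm_length must be positive")
  if (any(ptt <= 0, na.rm = TRUE)) stop_data("ptt must be positive")
  arm_length / (ptt / 1000)
}

#' Per-beat mean arterial pressure
#'
#' MAP is extracted directly from the continuous pressure signal as the
#' time-average over each beat's window (consecutive R times, half-open; the
#' final beat's window extends to the end of the record). Windows overlapping
#' a calibration gap yield `NA`.
#'
#' @param bp A [sampled_signal()] pressure channel.
#' @param r_times R-peak times, s.
#' @param calibration_gaps Optional data.frame with `start`, `end` (s).
#' @return Numeric vector of per-beat MAP, mmHg.
#' @export
extract_map_series <- function(bp, r_times, calibration_gaps = NULL) {
  nb <- length(r_times)
  t_end <- bp$start_time + length(bp$values) / bp$fs
  ends <- c(r_times[-1L], t_end)
  out <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    if (!is.null(calibration_gaps) && nrow(calibration_gaps) &&
        any(r_times[i] < calibration_gaps$end & ends[i] > calibration_gaps$start))
      next
    i0 <- as.integer(ceiling((r_times[i] - bp$start_time) * bp$fs - 1e-9)) + 1L
    i1 <- as.integer(ceiling((ends[i] - bp$start_time) * bp$fs - 1e-9))
    if (i0 > length(bp$values) || i1 < i0) next
    out[i] <- mean(bp$values[i0:min(i1, length(bp$values))])
  }
  out
}

#' Times of RRI-series peaks (heart-rate troughs)
#'
#' Local maxima of the beat-indexed RRI series, timestamped by the R time of
#' the beat with the locally longest interval. Used to localize the RSA proxy.
#'
#' @param beat_table A beat table with `r_time`, `rri`.
#' @return Numeric vector of times, s.
#' @export
rri_signal_peaks <- function(beat_table) {
  ok <- !is.na(beat_table$rri)
  v <- beat_table$rri[ok]
  tt <- beat_table$r_time[ok]
  tt[local_maxima(v)]
}

#' Peak-to-peak respiratory sinus arrhythmia proxy
#'
#' For each eligible breath (every breath during the baseline task, sighs only
#' during the sighing tasks), the RSA proxy is the delay from the respiration
#' peak to the next RRI-series peak (heart-rate trough). Longer delays
#' indicate stronger cardiorespiratory synchronization. Events with no RRI
#' peak within `max_delay_s` are left undefined (dropped from summaries) with
#' a warning.
#'
#' @param breaths data.frame from [detect_resp_peaks()].
#' @param rri_peak_times Times of RRI-series peaks, s (see
#'   [rri_signal_peaks()]).
#' @param task_label `"baseline"`, `"long_interval"` or `"short_interval"`.
#' @param max_delay_s Longest admissible delay, s (about one breath period).
#' @return data.frame with `resp_peak_time`, `is_sigh`, `rsa_delay` (s, `NA`
#'   when undefined).
#' @export
compute_rsa_events <- function(breaths, rri_peak_times, task_label,
                               max_delay_s = 4) {
  eligible <- if (task_label == "baseline") rep(TRUE, nrow(breaths)) else breaths$is_sigh
  ev <- breaths[eligible, , drop = FALSE]
  delay <- vapply(ev$resp_peak_time, function(tp) {
    nxt <- rri_peak_times[rri_peak_times > tp]
    if (!length(nxt)) return(NA_real_)
    d <- nxt[1] - tp
    if (d > max_delay_s) NA_real_ else d
  }, numeric(1))
  if (anyNA(delay))
    warning(sum(is.na(delay)), " breath event(s) without a matching RRI peak dropped")
  ev$rsa_delay <- delay
  rownames(ev) <- NULL
  ev
}
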