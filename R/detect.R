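# Event detection on the filtered channels.

# local maxima indices (plateau-tolerant: left >=, right >)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# greedy refractory pruning: keep highest peaks first, reject any candidate
# closer than min_dist samples to an accepted one
prune_refractory <- function(idx, heights, min_dist) {
  if (length(idx) == 0L) return(integer(0))
  ord <- idx[order(heights, decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Detect R-wave peaks on a (filtered) ECG channel
#'
#' Local maxima above an adaptive amplitude threshold, with a 250-ms
#' refractory period enforced greedily from the tallest candidate down.
#' The threshold is a fraction of the robust spike height (99th percentile
#' above the median).
#'
#' @param ecg A [sampled_signal()], ideally after [lowpass_filter()].
#' @param threshold_frac Fraction of the robust spike height (default 0.5).
#' @param refractory_s Minimum inter-peak distance, s (default 0.25).
#' @return Numeric vector of R-peak times, s (sample resolution). Empty, with
#'   a warning, for flat input.
#' @export
detect_r_peaks <- function(ecg, threshold_frac = 0.5, refractory_s = 0.25) {
  if (!inherits(ecg, "sampled_signal")) stop_config("ecg must be a sampled_signal")
  v <- ecg$values
  med <- stats::median(v)
  spike <- stats::quantile(v, 0.99, names = FALSE) - med
  if (!is.finite(spike) || spike <= 10 * .Machine$double.eps * max(1, abs(med))) {
    warning("flat ECG signal: no R peaks detected")
    return(numeric(0))
  }
  thr <- med + threshold_frac * spike
  cand <- local_maxima(v)
  cand <- cand[v[cand] > thr]
  keep <- prune_refractory(cand, v[cand], as.integer(round(refractory_s * ecg$fs)))
  ecg$start_time + (keep - 1) / ecg$fs
}

#' Detect per-beat systolic pressure peaks
#'
#' For each R peak, the maximum of the pressure signal within the half-open
#' search window `(R + 50 ms, next R)`; the window excludes the R-wave
#' artifact and guarantees the *subsequent* pulse peak. Ties break to the
#' earliest sample. Beats whose window contains no samples (end of record)
#' yield `NA`.
#'
#' @param bp A [sampled_signal()] pressure channel.
#' @param r_times Sorted R-peak times, s.
#' @param guard_s Window start offset after the R peak, s (default 0.05).
#' @return data.frame with `bp_peak_time` (s) and `sbp` (mmHg), one row per R.
#' @export
detect_bp_peaks <- function(bp, r_times, guard_s = 0.05) {
  if (!inherits(bp, "sampled_signal")) stop_config("bp must be a sampled_signal")
  if (is.unsorted(r_times, strictly = TRUE)) stop_data("r_times must be strictly increasing")
  tt <- signal_times(bp)
  t_end <- bp$start_time + length(bp$values) / bp$fs
  nb <- length(r_times)
  out <- data.frame(bp_peak_time = rep(NA_real_, nb), sbp = rep(NA_real_, nb))
  bounds <- c(r_times[-1L], t_end)
  for (i in seq_len(nb)) {
    i0 <- as.integer(ceiling((r_times[i] + guard_s - bp$start_time) * bp$fs)) + 1L
    i1 <- as.integer(ceiling((bounds[i] - bp$start_time) * bp$fs - 1e-9))
    if (i0 > length(bp$values) || i1 < i0) next
    i1 <- min(i1, length(bp$values))
    w <- bp$values[i0:i1]
    j <- which.max(w)            # earliest index on ties
    out$bp_peak_time[i] <- tt[i0 + j - 1L]
    out$sbp[i] <- w[j]
  }
  out
}

#' Detect breath peaks on the respiration channel
#'
#' Prominence-thresholded local maxima with a minimum inter-peak distance.
#' Peaks within `cue_tol_s` of a protocol sigh cue are flagged `is_sigh`.
#'
#' @param resp A [sampled_signal()] respiration channel (filtered).
#' @param cues Numeric vector of sigh cue onset times, s (may be empty).
#' @param min_distance_s Minimum spacing between breath peaks, s.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   signal's robust amplitude range.
#' @param cue_tol_s Matching tolerance to a cue, s (default 2).
#' @return data.frame with `resp_peak_time` (s) and `is_sigh` (logical).
#' @export
detect_resp_peaks <- function(resp, cues = numeric(0), min_distance_s = 2,
                              prominence_frac = 0.25, cue_tol_s = 2) {
  if (!inherits(resp, "sampled_signal")) stop_config("resp must be a sampled_signal")
  v <- resp$values
  if (length(v) < 3L)
    return(data.frame(resp_peak_time = numeric(0), is_sigh = logical(0)))
  rng <- stats::quantile(v, c(0.05, 0.95), names = FALSE)
  amp <- rng[2] - rng[1]
  if (amp <= 10 * .Machine$double.eps)
    return(data.frame(resp_peak_time = numeric(0), is_sigh = logical(0)))
  cand <- local_maxima(v)
  cand <- prune_refractory(cand, v[cand],
                           as.integer(round(min_distance_s * resp$fs)))
  # prominence within a local window: drop to the lowest valley on the
  # shallower side between neighbouring higher points
  half_win <- as.integer(round(5 * min_distance_s * resp$fs))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    lo <- max(1L, i - half_win)
    hi <- min(length(v), i + half_win)
    left <- v[lo:(i - 1L)]
    li <- which(left > h)
    lmin <- if (length(li) && max(li) < length(left)) {
      min(left[(max(li) + 1L):length(left)])
    } else min(left)
    right <- v[(i + 1L):hi]
    ri <- which(right > h)
    rmin <- if (length(ri) && min(ri) > 1L) {
      min(right[seq_len(min(ri) - 1L)])
    } else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= prominence_frac * amp]
  times <- resp$start_time + (keep - 1) / resp$fs
  # at most one sigh per cue: the tallest detected peak within tol of the cue
  is_sigh <- rep(FALSE, length(times))
  h <- v[keep]
  for (cu in cues) {
    cand_i <- which(abs(times - cu) <= cue_tol_s)
    if (length(cand_i)) is_sigh[cand_i[which.max(h[cand_i])]] <- TRUE
  }
  data.frame(resp_peak_time = times, is_sigh = is_sigh)
}
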