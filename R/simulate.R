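# Multi-channel recording simulator.
#
# Beat generation follows the integral pulse frequency modulation (IPFM)
# convention: an instantaneous R-to-R interval signal RRI(t) is integrated and
# a beat is emitted whenever the accumulated phase crosses an integer. RRI(t)
# is the sum of the subject mean, a delayed respiratory coupling (RSA), a
# ~0.1 Hz Mayer-wave oscillation, per-sigh dip kernels, and band-limited
# noise, floored at a physiological refractory minimum.

# internal rendering constants (sigh respiration bolus shape)
.sigh_resp_amplitude <- 3.0   # bolus height, eupneic amplitude = 1
.sigh_rise_s <- 0.5           # inhale-side Gaussian SD, s
.sigh_fall_s <- 1.2           # exhale-side Gaussian SD, s
.ecg_spike_sd_s <- 0.010      # R spike Gaussian SD, s
.ptt_noise_trunc <- 2.2       # per-beat PTT noise truncated at this many SDs

#' Simulate one participant's multi-channel recording
#'
#' Renders ECG-like, continuous arterial pressure, and respiration channels
#' over a full protocol timeline, together with the programmed ground truth
#' (beat times, per-beat RRI/PTT/SBP/MAP, breath peaks, RSA delay).
#'
#' @param params A [subject_params()].
#' @param timeline A [build_protocol()] timeline.
#' @param seed Integer seed; identical `(params, timeline, seed)` reproduce
#'   the recording bit-identically.
#' @param fs Sampling rate, Hz (default 250; configurable up to 2000).
#' @param insert_calibration_gaps If `TRUE`, one 10-s pressure-calibration gap
#'   is inserted per task (flat pressure trace) to exercise the downstream
#'   exclusion rule.
#' @param inhale_offset_s Latency from cue onset to peak inhalation, s.
#' @param rri_floor_ms Refractory floor on the instantaneous RRI, ms.
#' @return An object of class `fivs_recording`: `channels` (named list of
#'   equal-length numeric vectors `ecg`, `bp`, `resp`), `fs`,
#'   `calibration_gaps` (data.frame `start`, `end`), and `ground_truth` (list
#'   with `beats`, `breaths`, `rsa_delay`, `inhalation_peaks`).
#' @export
simulate_participant <- function(params, timeline, seed, fs = 250,
                                 insert_calibration_gaps = FALSE,
                                 inhale_offset_s = 1.0,
                                 rri_floor_ms = 520) {
  if (!inherits(params, "subject_params")) stop_config("params must be subject_params")
  if (!inherits(timeline, "fivs_protocol")) stop_config("timeline must be a fivs_protocol")
  if (missing(seed) || !is.finite(seed)) stop_config("an integer seed is required")
  if (fs <= 20 || fs > 2000) stop_config("fs must lie in (20, 2000] Hz")
  set.seed(as.integer(seed))

  total_s <- max(timeline$segments$end)
  n <- as.integer(round(total_s * fs))
  t <- (seq_len(n) - 1) / fs
  f_b <- params$eupneic_rate / 60
  inh <- segment_cues(timeline, "long_interval")
  inh <- c(inh, segment_cues(timeline, "short_interval")) + inhale_offset_s
  inh <- sort(inh)
  gain <- params$response_gain

  # respiration: eupneic sinusoid + asymmetric sigh boluses
  resp_clean <- sin(2 * pi * f_b * t)
  add_local <- function(x, centre, halfwidth_s, f) {
    i0 <- max(1L, as.integer(floor((centre - halfwidth_s) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((centre + halfwidth_s) * fs)) + 1L)
    if (i0 > n || i1 < 1L) return(x)
    idx <- i0:i1
    x[idx] <- x[idx] + f(t[idx] - centre)
    x
  }
  bolus <- function(dt) {
    s <- ifelse(dt < 0, .sigh_rise_s, .sigh_fall_s)
    .sigh_resp_amplitude * exp(-dt^2 / (2 * s^2))
  }
  for (ti in inh) resp_clean <- add_local(resp_clean, ti, 6, bolus)

  # task-dependent gains; the physiological state drawn for a segment
  # persists through the following inter-task gap
  short_seg <- timeline$segments[timeline$segments$label == "short_interval", ]
  in_short <- function(tt) tt >= short_seg$start & tt < short_seg$end
  seg_of <- function(tt) pmax(1L, findInterval(tt, timeline$segments$start))
  d_rri <- stats::rnorm(3, 0, params$rri_task_sd)
  d_bp <- stats::rnorm(3, 0, params$bp_task_sd)
  d_ptt <- pmin(pmax(stats::rnorm(3, 0, params$ptt_task_sd),
                     -3 * params$ptt_task_sd), 3 * params$ptt_task_sd)
  g_mult <- exp(stats::rnorm(3, 0, params$gain_task_sd))
  seg_t <- seg_of(t)
  rsa_gain_t <- params$rsa_gain * g_mult[seg_t] *
    ifelse(in_short(t), params$short_rsa_mult, 1)

  # instantaneous RRI (ms)
  phi_lf <- stats::runif(1, 0, 2 * pi)
  rri_inst <- params$mean_rri + d_rri[seg_t] +
    rsa_gain_t * sin(2 * pi * f_b * (t - params$rsa_delay)) +
    g_mult[seg_t] * params$lf_osc_amplitude *
      sin(2 * pi * params$lf_osc_freq * t + phi_lf)
  dip <- function(dt) -gain * params$kernel$rri_dip_amplitude *
    exp(-dt^2 / (2 * params$kernel$rri_dip_width^2))
  for (ti in inh) rri_inst <- add_local(rri_inst, ti, 6 * params$kernel$rri_dip_width, dip)
  if (params$rri_noise_sd > 0) {
    knots <- seq(0, total_s + 1, by = 1)
    kv <- stats::rnorm(length(knots), 0, params$rri_noise_sd)
    rri_inst <- rri_inst + stats::spline(knots, kv, xout = t, method = "natural")$y
  }
  rri_inst <- pmax(rri_inst, rri_floor_ms)

  # IPFM beat emission: phase crosses integers
  phase <- cumsum(1000 / rri_inst) / fs
  k <- floor(phase)
  cross <- which(diff(k) >= 1L)          # beat between sample i and i+1
  frac <- (k[cross + 1L] - phase[cross]) / (phase[cross + 1L] - phase[cross])
  r_times <- t[cross] + frac / fs
  if (length(r_times) < 3L) stop_infeasible("fewer than 3 beats generated")
  nb <- length(r_times)

  # per-beat PTT (ms), truncated noise keeps the BP peak ahead of the next R
  seg_b <- seg_of(r_times)
  ptt <- params$baseline_ptt + d_ptt[seg_b]
  for (ti in inh) {
    dt <- r_times - ti
    w <- abs(dt) < 6 * params$kernel$ptt_rise_width
    ptt[w] <- ptt[w] + gain * params$kernel$ptt_rise_amplitude *
      exp(-dt[w]^2 / (2 * params$kernel$ptt_rise_width^2))
  }
  if (params$ptt_noise_sd > 0) {
    z <- stats::rnorm(nb)
    z <- pmin(pmax(z, -.ptt_noise_trunc), .ptt_noise_trunc)
    # vasomotor variability grows with task load, more so in strong responders
    mult <- 1 + (params$ptt_noise_task_mult[seg_b] - 1) * gain
    ptt <- ptt + params$ptt_noise_sd * mult * z
  }
  bp_peak_t <- r_times + ptt / 1000
  next_r <- c(r_times[-1L], Inf)
  if (any(bp_peak_t >= next_r))
    stop_infeasible("PTT exceeds the beat interval: BP peak would fall after the next R wave")

  # per-beat systolic and diastolic pressure (mmHg)
  seg_p <- seg_of(bp_peak_t)
  short_add <- params$short_map_gain_mmhg * in_short(bp_peak_t) + d_bp[seg_p]
  sbp <- params$baseline_sbp + short_add +
    g_mult[seg_p] * params$lf_sbp_amplitude *
      sin(2 * pi * params$lf_osc_freq * bp_peak_t + phi_lf)
  for (ti in inh) {
    sbp <- sbp + gain * sigh_response_kernel(bp_peak_t - ti, params$kernel,
                                             "bp", params$mean_rri)
  }
  # mechanical respiratory coupling into systolic pressure rides on the
  # eupneic pump only: the sigh's own pressure response is the bp kernel
  sbp <- sbp + params$resp_sbp_gain * sin(2 * pi * f_b * bp_peak_t)
  if (params$sbp_noise_sd > 0) {
    # the mechanical cost of sigh production raises beat-to-beat systolic
    # scatter equally in both sighing tasks
    nmult <- ifelse(seg_p >= 2L, params$sbp_noise_task_mult, 1)
    sbp <- sbp + stats::rnorm(nb, 0, params$sbp_noise_sd) * nmult
  }
  dbp <- params$baseline_dbp + short_add
  sbp <- pmax(sbp, dbp + 15)   # pulse pressure floor

  # render the pressure waveform: half-cosine rise to the systolic peak at
  # r + PTT, half-cosine decay to the next beat's diastolic level
  bp <- rep(params$baseline_dbp, n)
  i_r <- as.integer(floor(r_times * fs)) + 1L
  i_p <- as.integer(round(bp_peak_t * fs)) + 1L   # nearest sample: rendered peak within half a sample of r + PTT
  i_next <- c(i_r[-1L] - 1L, n)
  for (b in seq_len(nb)) {
    ip <- min(i_p[b], n); ir <- i_r[b]; ie <- min(i_next[b], n)
    if (ir > n) break
    if (ip > ir) {
      u <- (t[ir:ip] - r_times[b]) / (ptt[b] / 1000)
      bp[ir:ip] <- dbp[b] + (sbp[b] - dbp[b]) * 0.5 * (1 - cos(pi * pmin(u, 1)))
    }
    if (ie > ip) {
      d_next <- if (b < nb) dbp[b + 1L] else dbp[b]
      span <- t[ie] - bp_peak_t[b]
      if (span > 0) {
        u <- (t[ip:ie] - bp_peak_t[b]) / span
        bp[ip:ie] <- d_next + (sbp[b] - d_next) * 0.5 * (1 + cos(pi * pmax(u, 0)))
      }
    }
  }

  # ground-truth MAP: per-beat time-average of the clean waveform
  map <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    ie <- min(i_next[b], n)
    if (i_r[b] <= ie) map[b] <- mean(bp[i_r[b]:ie])
  }

  # calibration gaps: device recalibration flattens the pressure trace
  gaps <- data.frame(start = numeric(0), end = numeric(0))
  if (insert_calibration_gaps) {
    gs <- timeline$segments$start + 200
    gaps <- data.frame(start = gs, end = gs + 10)
    for (g in seq_len(nrow(gaps))) {
      idx <- which(t >= gaps$start[g] & t < gaps$end[g])
      bp[idx] <- params$baseline_dbp
    }
  }

  # ECG: narrow Gaussian R spikes
  ecg <- numeric(n)
  spike <- function(dt) exp(-dt^2 / (2 * .ecg_spike_sd_s^2))
  for (tb in r_times) ecg <- add_local(ecg, tb, 5 * .ecg_spike_sd_s, spike)

  if (params$ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, params$ecg_noise_sd)
  resp <- resp_clean
  if (params$resp_noise_sd > 0) resp <- resp + stats::rnorm(n, 0, params$resp_noise_sd)

  # ground-truth breath peaks: eupneic maxima plus sigh bolus peaks
  eup_pk <- seq((0.25 / f_b), total_s, by = 1 / f_b)
  near_sigh <- vapply(eup_pk, function(x) any(abs(x - inh) < 2), logical(1))
  breaths <- rbind(
    data.frame(time = eup_pk[!near_sigh], is_sigh = FALSE),
    data.frame(time = inh, is_sigh = TRUE)
  )
  breaths <- breaths[order(breaths$time), , drop = FALSE]
  rownames(breaths) <- NULL

  beats <- data.frame(
    time = r_times,
    rri = c(NA_real_, diff(r_times) * 1000),
    ptt = ptt, bp_peak_time = bp_peak_t, sbp = sbp, map = map,
    in_gap = in_any_gap(bp_peak_t, gaps)
  )
  stopifnot(all(diff(beats$time) > 0))

  structure(list(
    channels = list(ecg = ecg, bp = bp, resp = resp),
    fs = fs,
    calibration_gaps = gaps,
    ground_truth = list(beats = beats, breaths = breaths,
                        rsa_delay = params$rsa_delay,
                        inhalation_peaks = inh),
    params = params, timeline = timeline, seed = as.integer(seed)
  ), class = "fivs_recording")
}

in_any_gap <- function(times, gaps) {
  out <- rep(FALSE, length(times))
  for (g in seq_len(nrow(gaps)))
    out <- out | (times >= gaps$start[g] & times < gaps$end[g])
  out
}

#' @export
print.fivs_recording <- function(x, ...) {
  cat(sprintf("fivs_recording: %.0f s at %g Hz, %d beats, %d sigh cues, %d calibration gaps\n",
              length(x$channels$ecg) / x$fs, x$fs, nrow(x$ground_truth$beats),
              length(x$ground_truth$inhalation_peaks), nrow(x$calibration_gaps)))
  invisible(x)
}

#' Draw per-subject parameters for a simulated cohort
#'
#' Samples subject parameters around the sex-specific defaults of
#' [subject_params()] with the dispersions of [cohort_dispersions()], clipping
#' each draw to its physiological validity range. Sex is assigned by rounding
#' `n * fraction_female` (round-half-to-even).
#'
#' @param n Number of subjects.
#' @param fraction_female Proportion of female subjects in `[0, 1]`.
#' @param dispersions A [cohort_dispersions()] object.
#' @param seed Integer master seed.
#' @return List with `params` (list of `subject_params`), `seeds` (per-subject
#'   integer seeds derived from the master seed), and `sex` (character).
#' @export
draw_cohort_params <- function(n, fraction_female = 0.65,
                               dispersions = cohort_dispersions(), seed = 1) {
  if (n < 1) stop_config("n must be at least 1")
  if (fraction_female < 0 || fraction_female > 1)
    stop_config("fraction_female must lie in [0, 1]")
  if (!inherits(dispersions, "cohort_dispersions"))
    stop_config("dispersions must come from cohort_dispersions()")
  sdv <- unlist(dispersions[names(dispersions) != "scale"])
  if (any(!is.finite(sdv)) || any(sdv < 0))
    stop_config("dispersions must be non-negative")
  set.seed(as.integer(seed))
  n_f <- round(n * fraction_female)
  sex <- c(rep("F", n_f), rep("M", n - n_f))

  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  d <- dispersions
  params <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sex[i]
    base <- subject_params(sex = s)
    lag <- if (d$scale > 0) sample(c(2L, 3L), 1L) else 2L
    kern <- sigh_kernel(bp_lag_beats = lag)
    params[[i]] <- subject_params(
      sex = s,
      mean_rri = clip(stats::rnorm(1, base$mean_rri, d$mean_rri), 620, 1100),
      rsa_gain = clip(stats::rnorm(1, base$rsa_gain, d$rsa_gain), 10, 80),
      rsa_delay = clip(stats::rnorm(1, base$rsa_delay, d$rsa_delay), 0.2, 1.6),
      lf_osc_amplitude = clip(stats::rnorm(1, base$lf_osc_amplitude,
                                           d$lf_osc_amplitude), 2, 35),
      lf_osc_freq = clip(stats::rnorm(1, base$lf_osc_freq, d$lf_osc_freq),
                         0.08, 0.12),
      eupneic_rate = clip(stats::rnorm(1, base$eupneic_rate, d$eupneic_rate),
                          10, 22),
      baseline_sbp = clip(stats::rnorm(1, base$baseline_sbp, d$baseline_sbp),
                          95, 145),
      baseline_dbp = clip(stats::rnorm(1, base$baseline_dbp, d$baseline_dbp),
                          55, 85),
      baseline_ptt = clip(stats::rnorm(1, base$baseline_ptt, d$baseline_ptt),
                          180, 280),
      arm_length = clip(stats::rnorm(1, base$arm_length, d$arm_length),
                        0.5, 0.8),
      kernel = kern,
      response_gain = clip(stats::rnorm(1, base$response_gain,
                                        d$response_gain), 0.4, 1.6),
      ptt_noise_sd = clip(stats::rnorm(1, base$ptt_noise_sd,
                                       d$ptt_noise_sd[[s]]), 5, 45)
    )
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  list(params = params, seeds = seeds, sex = sex)
}

#' Simulate a cohort of participants
#'
#' @inheritParams draw_cohort_params
#' @inheritParams simulate_participant
#' @param keep_channels If `FALSE`, sampled channels are dropped (ground truth
#'   only) to bound memory for large cohorts.
#' @return List with `recordings` (list of [simulate_participant()] outputs,
#'   named `S001`...) and `truth` (data.frame: one row per subject with sex,
#'   seed, and the drawn parameters that downstream summaries consume).
#' @export
simulate_cohort <- function(n, fraction_female = 0.65,
                            dispersions = cohort_dispersions(), seed = 1,
                            fs = 250, insert_calibration_gaps = FALSE,
                            timeline = build_protocol(),
                            keep_channels = TRUE) {
  drawn <- draw_cohort_params(n, fraction_female, dispersions, seed)
  ids <- sprintf("S%03d", seq_len(n))
  recs <- vector("list", n)
  names(recs) <- ids
  for (i in seq_len(n)) {
    rec <- simulate_participant(drawn$params[[i]], timeline,
                                seed = drawn$seeds[i], fs = fs,
                                insert_calibration_gaps = insert_calibration_gaps)
    if (!keep_channels) rec$channels <- NULL
    recs[[i]] <- rec
  }
  truth <- data.frame(
    subject = ids,
    sex = drawn$sex,
    seed = drawn$seeds,
    mean_rri = vapply(drawn$params, `[[`, numeric(1), "mean_rri"),
    rsa_delay = vapply(drawn$params, `[[`, numeric(1), "rsa_delay"),
    arm_length = vapply(drawn$params, `[[`, numeric(1), "arm_length"),
    baseline_ptt = vapply(drawn$params, `[[`, numeric(1), "baseline_ptt"),
    response_gain = vapply(drawn$params, `[[`, numeric(1), "response_gain"),
    stringsAsFactors = FALSE
  )
  list(recordings = recs, truth = truth)
}
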