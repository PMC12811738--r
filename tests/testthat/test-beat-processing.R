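test_that("zero-phase low-pass passes DC and the passband, kills the stopband", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  dc <- sampled_signal(rep(3.5, length(t)), fs)
  # away from the forward-backward pass's edge transients
  expect_equal(lowpass_filter(dc)$values[500:4500], dc$values[500:4500],
               tolerance = 1e-6)
  hi <- sampled_signal(sin(2 * pi * 20 * t), fs)
  y <- lowpass_filter(hi)$values
  expect_lt(max(abs(y[500:4500])), 0.10)        # >= 90% attenuation at 20 Hz
  lo <- sampled_signal(sin(2 * pi * 0.25 * t), fs)
  z <- lowpass_filter(lo)$values
  expect_equal(max(abs(z[500:4500])), 1, tolerance = 0.01)
  expect_error(lowpass_filter(sampled_signal(t, fs), cutoff_hz = 125),
               class = "sighstress_config_error")
})

test_that("R-peak detection recovers every noiseless ground-truth beat within one sample", {
  rec <- noiseless_recording()
  fs <- rec$fs
  ecg <- lowpass_filter(sampled_signal(rec$channels$ecg, fs))
  r <- detect_r_peaks(ecg)
  gt <- rec$ground_truth$beats$time
  expect_equal(length(r), length(gt))
  expect_lt(max(abs(r - gt)), 1 / fs)
})

test_that("R-peak detection keeps >= 99% sensitivity at 10% spike-height noise", {
  fs <- 250
  set.seed(42)
  true_t <- cumsum(stats::runif(120, 0.7, 1.0))
  t <- seq(0, max(true_t) + 1, by = 1 / fs)
  ecg <- numeric(length(t))
  for (tb in true_t) ecg <- ecg + exp(-(t - tb)^2 / (2 * 0.01^2))
  ecg <- ecg + stats::rnorm(length(t), 0, 0.10)
  r <- detect_r_peaks(lowpass_filter(sampled_signal(ecg, fs)))
  hits <- vapply(true_t, function(tb) any(abs(r - tb) <= 2 / fs), logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("flat ECG yields an empty peak list with a warning", {
  flat <- sampled_signal(rep(0.2, 1000), 250)
  expect_warning(r <- detect_r_peaks(flat), "flat")
  expect_length(r, 0)
})

test_that("BP-peak search finds each beat's systolic peak in (R+50ms, next R)", {
  rec <- noiseless_recording()
  gt <- rec$ground_truth$beats
  bp <- sampled_signal(rec$channels$bp, rec$fs)
  pk <- detect_bp_peaks(bp, gt$time)
  in_range <- !is.na(pk$sbp)
  expect_gt(mean(in_range), 0.99)
  expect_lt(max(abs(pk$sbp[in_range] - gt$sbp[in_range])), 0.5)
  expect_lt(max(abs(pk$bp_peak_time[in_range] - gt$bp_peak_time[in_range])),
            1.5 / rec$fs)
  # flat pressure: every window returns the flat value at its earliest sample
  flat <- sampled_signal(rep(80, 250 * 10), 250)
  pf <- detect_bp_peaks(flat, c(1, 2, 3))
  expect_equal(pf$sbp, rep(80, 3))
  expect_equal(pf$bp_peak_time[1:2], c(1, 2) + 0.052, tolerance = 1 / 250)
  # beat whose window falls past the end of the record is undefined
  pe <- detect_bp_peaks(flat, c(5, 9.996))
  expect_true(is.na(pe$sbp[2]))
})

test_that("breath detection counts eupneic breaths and flags sighs near cues", {
  fs <- 25
  t <- seq(0, 300 - 1 / fs, by = 1 / fs)
  resp <- sin(2 * pi * 0.25 * t)                 # 15 breaths/min
  n <- detect_resp_peaks(sampled_signal(resp, fs))
  expect_lte(abs(nrow(n) - 75), 1)
  expect_false(any(n$is_sigh))
  # add a sigh bolus at the 120-s cue
  resp2 <- resp + 3 * exp(-(t - 121)^2 / (2 * 0.8^2))
  n2 <- detect_resp_peaks(sampled_signal(resp2, fs), cues = 120)
  flagged <- n2$resp_peak_time[n2$is_sigh]
  expect_length(flagged, 1)
  expect_lt(abs(flagged - 121), 0.5)
})

test_that("RRI series arithmetic and monotonicity contract", {
  expect_equal(compute_rri_series(c(0.0, 0.8, 1.65)), c(800, 850))
  expect_length(compute_rri_series(5), 0)
  expect_error(compute_rri_series(c(1, 0.5)), class = "sighstress_data_error")
})

test_that("artifact rule flags a doubled RRI, interpolates it, and is idempotent", {
  set.seed(1)
  r <- cumsum(rep(0.8, 60) + stats::rnorm(60, 0, 0.01))
  bt <- build_beat_table(r)
  clean <- correct_rri_artifacts(bt)
  expect_equal(attr(clean, "n_corrected"), 0)
  expect_equal(clean$rri, bt$rri)

  bt2 <- bt
  bt2$rri[30] <- bt2$rri[30] * 2                  # missed beat
  fixed <- correct_rri_artifacts(bt2)
  expect_true(fixed$artifact_corrected[30])
  nb_mean <- mean(bt2$rri[c(29, 31)])
  expect_lt(abs(fixed$rri[30] - nb_mean) / nb_mean, 0.10)
  again <- correct_rri_artifacts(fixed)
  expect_equal(attr(again, "n_corrected"), 0)
  expect_equal(again$rri, fixed$rri)
})

test_that("a 30%-corrupted record is rejected as a quality failure", {
  set.seed(2)
  r <- cumsum(rep(0.8, 100))
  bt <- build_beat_table(r)
  bad <- sample(2:100, 30)
  bt$rri[bad] <- bt$rri[bad] * 2
  expect_error(correct_rri_artifacts(bt), class = "sighstress_quality_error")
})

test_that("PTT is the R-to-BP-peak delay and negative PTT invalidates the beat", {
  bt <- build_beat_table(c(10, 10.8), data.frame(
    bp_peak_time = c(10.250, 10.7), sbp = c(120, 121)))
  bt <- compute_ptt_series(bt)
  expect_equal(bt$ptt[1], 250)
  bt2 <- build_beat_table(c(10, 10.8), data.frame(
    bp_peak_time = c(9.9, NA), sbp = c(120, NA)))
  bt2 <- compute_ptt_series(bt2)
  expect_true(bt2$excluded[1])
  expect_true(is.na(bt2$ptt[1]))
  expect_true(is.na(bt2$ptt[2]))
})

test_that("noiseless pipeline PTT matches the programmed PTT within one sample", {
  pr <- noiseless_processed()
  rec <- noiseless_recording()
  gt <- rec$ground_truth$beats
  bt <- pr$beat_table
  idx <- match_beats(bt$r_time, gt$time)
  ok <- !is.na(bt$ptt)
  expect_lt(max(abs(bt$ptt[ok] - gt$ptt[idx][ok])), 1000 / rec$fs)
  expect_lt(max(abs(bt$rri[-1] - gt$rri[idx][-1]), na.rm = TRUE),
            1000 / rec$fs)
})

test_that("calibration-gap flagging counts beats by BP-peak time and merges gaps", {
  bt <- build_beat_table(seq(0.5, 299.5, by = 1), data.frame(
    bp_peak_time = seq(0.5, 299.5, by = 1) + 0.25,
    sbp = rep(120, 300)))
  out <- apply_calibration_exclusion(bt, data.frame(start = 100, end = 110))
  expect_equal(sum(out$in_calibration), 10)
  # overlapping gaps merge silently
  out2 <- apply_calibration_exclusion(bt, data.frame(
    start = c(100, 105), end = c(110, 112)))
  expect_equal(sum(out2$in_calibration), 12)
  expect_equal(sum(apply_calibration_exclusion(
    bt, data.frame(start = numeric(0), end = numeric(0)))$in_calibration), 0)
})

test_that("pulse wave velocity is arm length over transit time", {
  expect_equal(compute_pwv(0.6, 200), 3.0)
  expect_equal(compute_pwv(0.6, 300), 2.0)
  set.seed(3)
  for (i in 1:20) {
    arm <- stats::runif(1, 0.4, 0.9)
    ptt <- stats::runif(1, 120, 350)
    expect_equal(compute_pwv(arm, ptt) * ptt / 1000, arm, tolerance = 1e-12)
  }
  expect_error(compute_pwv(-0.5, 200), class = "sighstress_config_error")
  expect_error(compute_pwv(0.6, -10), class = "sighstress_data_error")
})

test_that("per-beat MAP is the time-average of the pressure waveform", {
  fs <- 300
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  # square pulse: 120 mmHg for one third of each 1-s beat, 80 otherwise
  bp <- ifelse((t %% 1) < 1 / 3, 120, 80)
  m <- extract_map_series(sampled_signal(bp, fs), 0:9)
  expect_equal(m, rep(120 / 3 + 80 * 2 / 3, 10), tolerance = 0.05)
  const <- extract_map_series(sampled_signal(rep(90, 1000), 250), c(0, 1, 2))
  expect_equal(const, rep(90, 3))
  # window overlapping a calibration gap is undefined
  g <- extract_map_series(sampled_signal(bp, fs), 0:9,
                          data.frame(start = 4.2, end = 5.1))
  expect_true(all(is.na(g[5:6])))
  expect_false(anyNA(g[c(1:4, 7:10)]))
})

test_that("RSA events use every baseline breath but only sighs during tasks", {
  breaths <- data.frame(resp_peak_time = c(10, 14, 18, 22),
                        is_sigh = c(FALSE, TRUE, FALSE, TRUE))
  rri_pk <- c(10.75, 14.6, 18.9, 23.2)
  base <- compute_rsa_events(breaths, rri_pk, "baseline")
  expect_equal(nrow(base), 4)
  expect_equal(base$rsa_delay[1], 0.75)
  task <- compute_rsa_events(breaths, rri_pk, "long_interval")
  expect_equal(nrow(task), 2)
  expect_true(all(task$is_sigh))
  # no RRI peak within one breath period -> undefined, with a warning
  expect_warning(
    miss <- compute_rsa_events(data.frame(resp_peak_time = 50, is_sigh = FALSE),
                               rri_pk, "baseline", max_delay_s = 4))
  expect_true(is.na(miss$rsa_delay))
})

test_that("programmed RSA delay is recovered within one beat spacing", {
  pr <- noiseless_processed()
  rec <- noiseless_recording()
  ev <- pr$breaths[pr$breaths$task == "baseline", ]
  beat_spacing <- mean(diff(rec$ground_truth$beats$time))
  expect_lt(abs(mean(ev$rsa_delay, na.rm = TRUE) - rec$ground_truth$rsa_delay),
            beat_spacing)
  # baseline task: one RSA value available per detected breath (up to count)
  expect_lte(nrow(ev), 80)
  expect_gte(sum(!is.na(ev$rsa_delay)), 60)
  # sighing tasks: exactly the sigh events are eligible
  lng <- pr$breaths[pr$breaths$task == "long_interval", ]
  expect_equal(nrow(lng), 10)
})
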