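test_that("sigh response kernels peak where physiology says they should", {
  k <- sigh_kernel()
  # RRI dip and PTT rise peak at the inhalation peak
  expect_equal(sigh_response_kernel(0, k, "rri"), -k$rri_dip_amplitude)
  expect_equal(sigh_response_kernel(0, k, "ptt"), k$ptt_rise_amplitude)
  tg <- seq(-5, 10, by = 0.001)
  expect_equal(tg[which.min(sigh_response_kernel(tg, k, "rri"))], 0)
  # BP kernel peaks bp_lag_beats mean beats after the inhalation peak
  bp <- sigh_response_kernel(tg, k, "bp", mean_rri_ms = 800)
  expect_equal(tg[which.max(bp)], 2 * 0.8, tolerance = 1e-3)
  expect_equal(max(bp), k$bp_rise_amplitude, tolerance = 1e-9)
})

test_that("kernel deflections decay to zero away from the sigh", {
  k <- sigh_kernel()
  for (ch in c("rri", "ptt", "bp")) {
    expect_lt(abs(sigh_response_kernel(60, k, ch, 800)),
              0.05 * k$bp_rise_amplitude)
    expect_lt(abs(sigh_response_kernel(-60, k, ch, 800)), 1e-10)
  }
  # recovery essentially complete within 15 s at defaults
  expect_lt(abs(sigh_response_kernel(15, k, "bp", 800)),
            0.05 * k$bp_rise_amplitude)
  expect_error(sigh_response_kernel(0, k, "resp"))
  expect_error(sigh_kernel(bp_lag_beats = 4), class = "sighstress_config_error")
  expect_error(sigh_kernel(rri_dip_amplitude = -1),
               class = "sighstress_config_error")
})

test_that("constant physiology yields constant RRI and PTT at the programmed values", {
  p <- constant_params()
  rec <- simulate_participant(p, build_protocol(), seed = 1)
  gt <- rec$ground_truth$beats
  expect_true(all(abs(gt$rri[-1] - p$mean_rri) < 1e-6))
  expect_true(all(abs(gt$ptt - p$baseline_ptt) < 1e-9))
  # integrate-to-threshold beat count over the baseline segment
  n_base <- sum(gt$time >= 0 & gt$time < 300)
  expect_lte(abs(n_base - 300 / (p$mean_rri / 1000)), 2)
})

test_that("identical seeds reproduce recordings bit-identically", {
  p <- subject_params("F")
  tl <- build_protocol()
  a <- simulate_participant(p, tl, seed = 77)
  b <- simulate_participant(p, tl, seed = 77)
  expect_identical(a$channels, b$channels)
  expect_identical(a$ground_truth$beats, b$ground_truth$beats)
  d <- simulate_participant(p, tl, seed = 78)
  expect_false(identical(a$channels$ecg, d$channels$ecg))
})

test_that("ground-truth beat times are strictly increasing and finite", {
  rec <- noiseless_recording()
  gt <- rec$ground_truth$beats
  expect_true(all(diff(gt$time) > 0))
  expect_true(all(is.finite(gt$time)))
  expect_true(all(is.finite(gt$ptt)))
  expect_true(all(is.finite(gt$sbp)))
  n <- length(rec$channels$ecg)
  expect_identical(lengths(rec$channels), c(ecg = n, bp = n, resp = n))
})

test_that("a PTT reaching the next beat aborts the simulation as infeasible", {
  p <- subject_params("M", mean_rri = 600, baseline_ptt = 340,
                      kernel = sigh_kernel(ptt_rise_amplitude = 250,
                                           ptt_rise_width = 2),
                      rri_noise_sd = 0, ptt_noise_sd = 0)
  expect_error(
    simulate_participant(p, build_protocol(), seed = 1, rri_floor_ms = 450),
    class = "sighstress_infeasible_error")
})

test_that("cohort sex split follows the rounding rule and zero dispersion collapses draws", {
  drawn <- draw_cohort_params(250, 0.65, seed = 5)
  expect_true(sum(drawn$sex == "F") %in% c(162, 163))
  one <- draw_cohort_params(1, 0, seed = 5)
  expect_equal(one$sex, "M")
  z <- draw_cohort_params(20, 0.5, cohort_dispersions(scale = 0), seed = 5)
  f_idx <- which(z$sex == "F")
  m_idx <- which(z$sex == "M")
  expect_identical(z$params[[f_idx[1]]], z$params[[f_idx[2]]])
  expect_identical(z$params[[m_idx[1]]], z$params[[m_idx[2]]])
  expect_error(cohort_dispersions(scale = -1),
               class = "sighstress_config_error")
  expect_error(draw_cohort_params(0, 0.5), class = "sighstress_config_error")
})

test_that("subject parameter validation enforces physiological ranges", {
  expect_error(subject_params("M", mean_rri = 500),
               class = "sighstress_config_error")
  expect_error(subject_params("F", eupneic_rate = 30),
               class = "sighstress_config_error")
  expect_error(subject_params("F", baseline_ptt = 100),
               class = "sighstress_config_error")
  expect_error(subject_params("F", ptt_noise_sd = -1),
               class = "sighstress_config_error")
})

test_that("calibration gaps are inserted once per task and recorded", {
  p <- noiseless_params()
  rec <- simulate_participant(p, build_protocol(), seed = 9,
                              insert_calibration_gaps = TRUE)
  expect_equal(nrow(rec$calibration_gaps), 3)
  expect_equal(rec$calibration_gaps$end - rec$calibration_gaps$start,
               rep(10, 3))
  gt <- rec$ground_truth$beats
  expect_true(any(gt$in_gap))
})
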