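test_that("spline resampling is exact on constants and lines, faithful on tones", {
  tt <- cumsum(stats::runif(40, 0.7, 0.9))
  cs <- resample_to_uniform(rep(800, 40), tt)
  expect_true(all(abs(cs$values - 800) < 1e-9))
  ln <- resample_to_uniform(500 + 3 * tt, tt)
  grid <- cs$start_time + (seq_along(ln$values) - 1) / 4
  expect_equal(ln$values, 500 + 3 * grid, tolerance = 1e-6)
  set.seed(8)
  bt <- cumsum(stats::runif(260, 0.7, 0.9))
  sine <- 40 * sin(2 * pi * 0.1 * bt)
  rs <- resample_to_uniform(sine, bt)
  g <- rs$start_time + (seq_along(rs$values) - 1) / 4
  expect_gt(stats::cor(rs$values, 40 * sin(2 * pi * 0.1 * g)), 0.999)
  expect_error(resample_to_uniform(c(1, 2, 3), c(1, 2, 3)),
               class = "sighstress_data_error")
})

test_that("Welch PSD recovers a tone's A^2/2 band power and segment count", {
  t <- seq(0, 300 - 0.25, by = 0.25)
  x <- 40 * sin(2 * pi * 0.10 * t)
  sp <- welch_psd(x, rate = 4)
  expect_equal(sp$meta$n_segments, 9)
  p <- integrate_band(sp, 0.08, 0.12)
  expect_equal(p, 40^2 / 2, tolerance = 0.05)
  # constant series: detrending leaves essentially zero power
  spc <- welch_psd(rep(5, 1200), rate = 4)
  expect_lt(integrate_band(spc, 0.01, 2), 1e-10)
  expect_error(welch_psd(rnorm(100), rate = 4),
               class = "sighstress_data_error")
})

test_that("Parseval holds within 10% on seeded white noise, across many seeds", {
  fails <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- stats::rnorm(1200, sd = 3)
    sp <- welch_psd(x, rate = 4)
    tot <- integrate_band(sp, 0, 2)
    if (abs(tot - stats::var(x)) / stats::var(x) > 0.10) fails <- fails + 1
  }
  expect_lte(fails, 5)
})

test_that("frequency axis is correct: tone argmax within one bin of the truth", {
  t <- seq(0, 300 - 0.25, by = 0.25)
  bin <- 4 / 2048
  for (f0 in c(0.033, 0.066, 0.1, 0.25)) {
    sp <- welch_psd(20 * sin(2 * pi * f0 * t), rate = 4)
    amax <- sp$freq[which.max(sp$psd)]
    expect_lte(abs(amax - f0), bin + 1e-9)
  }
})

test_that("band powers integrate half-open bands exactly on a flat spectrum", {
  freq <- seq(0, 2, by = 4 / 2048)
  flat <- structure(list(freq = freq, psd = rep(100, length(freq)),
                         meta = list(rate = 4)), class = "fivs_psd")
  lf <- band_power(flat, "LF")
  expect_equal(lf$power, 11)                      # 0.11 Hz x 100
  expect_equal(lf$ln_power, log(11), tolerance = 1e-9)
  expect_equal(band_power(flat, "HF")$power, 25)  # 0.25 Hz x 100
  zero <- structure(list(freq = freq, psd = rep(0, length(freq)),
                         meta = list(rate = 4)), class = "fivs_psd")
  expect_warning(bp0 <- band_power(zero, "LF"), "non-positive")
  expect_true(is.na(bp0$ln_power))
})

test_that("a 0.30-Hz tone lands in HF, not LF, and VLF power is never summed", {
  t <- seq(0, 300 - 0.25, by = 0.25)
  sp <- welch_psd(20 * sin(2 * pi * 0.30 * t), rate = 4)
  tot <- integrate_band(sp, 0.005, 2)
  expect_gt(band_power(sp, "HF")$power / tot, 0.95)
  expect_lt(band_power(sp, "LF")$power / tot, 0.01)
  # a VLF tone contributes nothing to either reported band
  spv <- welch_psd(20 * sin(2 * pi * 0.02 * t), rate = 4)
  expect_lt(band_power(spv, "LF")$power, 0.02 * integrate_band(spv, 0.005, 2))
  expect_lt(band_power(spv, "HF")$power, 0.01 * integrate_band(spv, 0.005, 2))
})

test_that("LF + HF power never exceeds the total spectral power", {
  set.seed(12)
  for (i in 1:10) {
    x <- stats::rnorm(1200)
    sp <- welch_psd(x, rate = 4)
    expect_lte(band_power(sp, "LF")$power + band_power(sp, "HF")$power,
               integrate_band(sp, 0, 2) + 1e-12)
  }
})

test_that("task summary converts mean RRI to HR and degrades gracefully", {
  bt <- build_beat_table(seq(0, 40, by = 0.8))
  bt$map <- 90
  row <- summarize_task(bt, NULL, list(rri = NULL, sbp = NULL),
                        "baseline", "S1", "F", 0.65)
  expect_equal(row$hr, 75)                        # 60000 / 800
  expect_true(is.na(row$ln_lf_hrv))
  expect_true(is.na(row$pttv) || row$pttv == 0)
  expect_equal(row$task, "baseline")
})

test_that("female subjects average faster heart rates than males at default parameters", {
  co <- small_cohort_spectra()
  base <- co$summary[co$summary$task == "baseline", ]
  expect_gt(mean(base$hr[base$sex == "F"]), mean(base$hr[base$sex == "M"]))
})
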