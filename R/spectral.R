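# Welch power spectral densities of the beat-to-beat series, and HRV/BPV
# band powers. Frequency bands follow short-term HRV convention:
# LF 0.04-0.15 Hz, HF 0.15-0.4 Hz; the VLF band (< 0.04 Hz) is excluded
# from all summaries.

#' Frequency band definitions
#' @return Named list of `c(lo, hi)` band edges, Hz (half-open intervals).
#' @export
hrv_bands <- function() list(LF = c(0.04, 0.15), HF = c(0.15, 0.40))

#' Resample a beat-indexed series onto a uniform grid
#'
#' Natural cubic-spline interpolation of per-beat values onto a uniform grid
#' spanning `[first, last]` beat time, at 4 Hz by default. Beats with missing
#' values (excluded, in-calibration) are interpolated across.
#'
#' @param beat_values Per-beat values (ms for RRI, mmHg for SBP).
#' @param beat_times Beat timestamps, s (R times for RRI, BP-peak times for
#'   SBP).
#' @param rate Grid rate, Hz (default 4).
#' @param source Label: `"rri"` or `"sbp"`.
#' @return Object of class `uniform_series`: `values`, `rate`, `start_time`,
#'   `source`.
#' @export
resample_to_uniform <- function(beat_values, beat_times, rate = 4,
                                source = "rri") {
  ok <- is.finite(beat_values) & is.finite(beat_times)
  x <- beat_times[ok]; y <- beat_values[ok]
  if (length(x) < 4L)
    stop_data("at least 4 valid beats are required for spline resampling")
  if (is.unsorted(x, strictly = TRUE)) stop_data("beat times must be increasing")
  grid <- seq(x[1], x[length(x)], by = 1 / rate)
  sf <- stats::splinefun(x, y, method = "natural")
  structure(list(values = sf(grid), rate = rate, start_time = x[1],
                 source = source),
            class = "uniform_series")
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

detrend_linear <- function(x) {
  n <- length(x)
  i <- seq_len(n)
  stats::lm.fit(cbind(1, i), x)$residuals
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hann-windowed, per-segment linearly detrended,
#' 50%-overlapping segments, each zero-padded to `nfft` points. The density is
#' one-sided and scaled so that its integral approximates the series variance
#' (Parseval). A 300-s series at 4 Hz with a 60-s window yields 9 segments.
#'
#' @param series A [resample_to_uniform()] `uniform_series`, or a numeric
#'   vector with `rate` given.
#' @param window_s Segment length, s (default 60).
#' @param overlap Fractional overlap (default 0.5).
#' @param nfft FFT size after zero-padding (default 2048).
#' @param rate Sampling rate when `series` is a bare vector.
#' @return Object of class `fivs_psd`: `freq` (Hz), `psd` (unit^2/Hz), and
#'   `meta` (window, segment count, detrend).
#' @export
welch_psd <- function(series, window_s = 60, overlap = 0.5, nfft = 2048,
                      rate = NULL) {
  if (inherits(series, "uniform_series")) {
    x <- series$values; fs <- series$rate; src <- series$source
  } else {
    if (is.null(rate)) stop_config("rate must be given for a bare vector")
    x <- as.numeric(series); fs <- rate; src <- "unknown"
  }
  nseg <- as.integer(round(window_s * fs))
  if (length(x) < nseg)
    stop_data("series shorter than one Welch window (", nseg, " samples)")
  if (nfft < nseg) stop_config("nfft must be at least the window length")
  hop <- as.integer(round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- hann(nseg)
  u <- sum(w^2)
  nf <- nfft %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- detrend_linear(x[s0:(s0 + nseg - 1L)]) * w
    X <- stats::fft(c(seg, numeric(nfft - nseg)))[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist for even nfft)
  dbl <- rep(2, nf); dbl[1] <- 1; if (nfft %% 2L == 0L) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd,
                 meta = list(window = "hann", window_s = window_s,
                             overlap = overlap, nfft = nfft,
                             n_segments = length(starts), rate = fs,
                             detrend = "linear per segment", source = src)),
            class = "fivs_psd")
}

#' @export
print.fivs_psd <- function(x, ...) {
  cat(sprintf("fivs_psd (%s): %d bins to %.3f Hz, %d Welch segments (%g-s Hann, %.0f%% overlap, nfft %d)\n",
              x$meta$source, length(x$freq), max(x$freq), x$meta$n_segments,
              x$meta$window_s, 100 * x$meta$overlap, x$meta$nfft))
  invisible(x)
}

# trapezoidal integral of a piecewise-linear psd over [lo, hi), with exact
# interpolation at the band edges
integrate_psd <- function(freq, psd, lo, hi) {
  if (lo < min(freq) || hi > max(freq))
    stop_config("spectrum does not cover the band [", lo, ", ", hi, ")")
  inside <- freq > lo & freq < hi
  f <- c(lo, freq[inside], hi)
  p <- c(stats::approx(freq, psd, xout = lo)$y, psd[inside],
         stats::approx(freq, psd, xout = hi)$y)
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Integrate a spectrum over an arbitrary band
#'
#' @param spectrum A [welch_psd()] object.
#' @param lo,hi Band edges, Hz (half-open `[lo, hi)`).
#' @return The trapezoidal integral (ms^2 or mmHg^2).
#' @export
integrate_band <- function(spectrum, lo, hi) {
  integrate_psd(spectrum$freq, spectrum$psd, lo, hi)
}

#' Band power of a spectrum
#'
#' Trapezoidal integral of the PSD over a half-open frequency band, on the
#' zero-padded Welch grid, plus its natural logarithm (the scale used for all
#' statistical modelling of band powers).
#'
#' @param spectrum A [welch_psd()] object.
#' @param band `"LF"`, `"HF"`, or a numeric `c(lo, hi)` in Hz.
#' @return List with `power` (ms^2 or mmHg^2) and `ln_power`; `ln_power` is
#'   `NA` with a warning when the power is not positive.
#' @export
band_power <- function(spectrum, band = "LF") {
  if (!inherits(spectrum, "fivs_psd")) stop_config("spectrum must be a fivs_psd")
  if (is.character(band)) {
    band <- hrv_bands()[[match.arg(band, names(hrv_bands()))]]
  }
  p <- integrate_psd(spectrum$freq, spectrum$psd, band[1], band[2])
  lp <- if (is.finite(p) && p > 0) log(p) else {
    warning("non-positive band power: ln undefined")
    NA_real_
  }
  list(power = p, ln_power = lp)
}

#' Average spectra across subjects
#'
#' @param spectra List of [welch_psd()] objects on identical frequency grids.
#' @return A `fivs_psd` whose psd is the pointwise mean.
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop_data("no spectra to average")
  f0 <- spectra[[1]]$freq
  for (s in spectra)
    if (!isTRUE(all.equal(s$freq, f0))) stop_data("spectra on different grids")
  m <- rowMeans(vapply(spectra, `[[`, numeric(length(f0)), "psd"))
  out <- spectra[[1]]
  out$psd <- m
  out$meta$n_averaged <- length(spectra)
  out
}

#' Locate spectral peaks above a local background
#'
#' Local maxima of the PSD within `range_hz` whose height exceeds
#' `min_ratio` times the local background (the median PSD within
#' `bg_halfwidth_hz`, excluding the peak's immediate neighbourhood). Used to
#' read the sighing-frequency signature and its harmonics off a
#' group-averaged spectrum.
#'
#' @param spectrum A [welch_psd()] object.
#' @param range_hz Frequency range searched (default `c(0, 0.2)`).
#' @param min_ratio Minimum peak-to-background ratio (default 3).
#' @param bg_halfwidth_hz Half-width of the background window, Hz.
#' @param exclude_bins Bins around the peak excluded from the background.
#' @return data.frame with `freq`, `psd`, `ratio`, ordered by frequency.
#' @export
spectral_peaks <- function(spectrum, range_hz = c(0, 0.2), min_ratio = 3,
                           bg_halfwidth_hz = 0.022, exclude_bins = 5L) {
  f <- spectrum$freq; p <- spectrum$psd
  cand <- local_maxima(p)
  cand <- cand[f[cand] > range_hz[1] & f[cand] <= range_hz[2]]
  rows <- lapply(cand, function(i) {
    win <- which(abs(f - f[i]) <= bg_halfwidth_hz & abs(seq_along(f) - i) > exclude_bins)
    if (!length(win)) return(NULL)
    bg <- stats::median(p[win])
    data.frame(freq = f[i], psd = p[i], ratio = p[i] / bg)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(freq = numeric(0), psd = numeric(0),
                                      ratio = numeric(0))
  out <- out[out$ratio >= min_ratio, , drop = FALSE]
  # collapse shoulders: keep the tallest peak within the exclusion window
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      close <- abs(out$freq - out$freq[i]) <= exclude_bins * (f[2] - f[1])
      if (any(out$psd[close] > out$psd[i])) keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Frequency of the sub-0.15 Hz spectral maximum
#'
#' @param spectrum A [welch_psd()] object (typically group averaged).
#' @param below_hz Upper frequency bound, Hz (default 0.15).
#' @param above_hz Lower bound excluding the DC/detrend residue (default
#'   0.01).
#' @return The argmax frequency, Hz.
#' @export
dominant_low_frequency <- function(spectrum, below_hz = 0.15, above_hz = 0.01) {
  sel <- spectrum$freq > above_hz & spectrum$freq < below_hz
  spectrum$freq[sel][which.max(spectrum$psd[sel])]
}
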