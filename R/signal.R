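#' Uniformly sampled signal container
#'
#' @param values Numeric samples (finite).
#' @param fs Sampling rate, Hz.
#' @param start_time Time of the first sample, s.
#' @return Object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, fs, start_time = 0) {
  if (!is.numeric(values)) stop_data("signal values must be numeric")
  if (any(!is.finite(values))) stop_data("signal values must be finite")
  if (!is.finite(fs) || fs <= 0) stop_config("sampling rate must be positive")
  structure(list(values = as.numeric(values), fs = fs,
                 start_time = start_time),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("sampled_signal: %d samples at %g Hz starting %.3f s\n",
              length(x$values), x$fs, x$start_time))
  invisible(x)
}

signal_times <- function(x) x$start_time + (seq_along(x$values) - 1) / x$fs

#' Slice a sampled signal to a half-open time window
#'
#' @param x A [sampled_signal()].
#' @param start,end Window bounds, s; samples with `start <= t < end` kept.
#' @return A [sampled_signal()] whose `start_time` is the first kept sample.
#' @export
slice_signal <- function(x, start, end) {
  i0 <- max(1L, as.integer(ceiling((start - x$start_time) * x$fs - 1e-9)) + 1L)
  i1 <- min(length(x$values),
            as.integer(ceiling((end - x$start_time) * x$fs - 1e-9)))
  if (i1 < i0) stop_data("empty signal slice")
  sampled_signal(x$values[i0:i1], x$fs, x$start_time + (i0 - 1) / x$fs)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth low-pass, so filtered
#' event times are not shifted relative to the raw signal.
#'
#' @param x A [sampled_signal()].
#' @param cutoff_hz Cutoff frequency, Hz (default 10, must be below Nyquist).
#' @param order Filter order before the forward-backward pass (default 4).
#' @return The filtered [sampled_signal()], same length and timing.
#' @export
lowpass_filter <- function(x, cutoff_hz = 10, order = 4) {
  if (!inherits(x, "sampled_signal")) stop_config("x must be a sampled_signal")
  if (cutoff_hz >= x$fs / 2)
    stop_config("cutoff must be below the Nyquist frequency ", x$fs / 2, " Hz")
  bf <- signal::butter(order, cutoff_hz / (x$fs / 2), type = "low")
  y <- signal::filtfilt(bf, x$values)
  sampled_signal(y, x$fs, x$start_time)
}
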