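#' Per-sigh cardiovascular response kernel
#'
#' Parameterizes the stereotyped phasic response to a single volitional sigh:
#' heart rate accelerates (R-to-R interval dips) in phase with peak
#' inhalation, pulse transit time rises (vasodilation) in phase with the
#' inhalation, and systolic blood pressure peaks two to three beats later
#' before recovering passively.
#'
#' The RRI and PTT deflections are Gaussian bumps centred at the inhalation
#' peak (`t_rel = 0`); the blood-pressure deflection is a gamma-shaped
#' rise/exponential decay whose mode sits `bp_lag_beats` mean beats after the
#' inhalation peak.
#'
#' @param rri_dip_amplitude Depth of the RRI dip, ms (> 0; the deflection
#'   applied is negative).
#' @param rri_dip_width Gaussian SD of the RRI dip, s.
#' @param ptt_rise_amplitude Height of the PTT rise, ms.
#' @param ptt_rise_width Gaussian SD of the PTT rise, s.
#' @param bp_rise_amplitude Height of the systolic pressure rise, mmHg.
#' @param bp_lag_beats Beats between peak inhalation and the BP peak (2 or 3).
#' @param bp_recovery_tau Exponential decay time constant of the BP rise, s.
#'
#' @return An object of class `sigh_kernel`.
#' @examples
#' k <- sigh_kernel()
#' sigh_response_kernel(0, k, "rri")      # -rri_dip_amplitude
#' @export
sigh_kernel <- function(rri_dip_amplitude = 150, rri_dip_width = 1.4,
                        ptt_rise_amplitude = 35, ptt_rise_width = 2.0,
                        bp_rise_amplitude = 12, bp_lag_beats = 2,
                        bp_recovery_tau = 0.5) {
  amps <- c(rri_dip_amplitude, ptt_rise_amplitude, bp_rise_amplitude)
  if (any(!is.finite(amps)) || any(amps <= 0))
    stop_config("sigh kernel amplitudes must be positive and finite")
  if (any(c(rri_dip_width, ptt_rise_width, bp_recovery_tau) <= 0))
    stop_config("sigh kernel widths and recovery tau must be positive")
  if (!bp_lag_beats %in% c(2, 3))
    stop_config("bp_lag_beats must be 2 or 3")
  structure(list(rri_dip_amplitude = rri_dip_amplitude,
                 rri_dip_width = rri_dip_width,
                 ptt_rise_amplitude = ptt_rise_amplitude,
                 ptt_rise_width = ptt_rise_width,
                 bp_rise_amplitude = bp_rise_amplitude,
                 bp_lag_beats = bp_lag_beats,
                 bp_recovery_tau = bp_recovery_tau),
            class = "sigh_kernel")
}

#' Evaluate a sigh response kernel
#'
#' @param t_rel Time relative to the sigh's inhalation peak, s (vectorized).
#' @param kernel A [sigh_kernel()].
#' @param which Channel: `"rri"` (ms, negative dip), `"ptt"` (ms, positive
#'   rise) or `"bp"` (mmHg, delayed positive rise).
#' @param mean_rri_ms Subject mean R-to-R interval, ms; sets the BP kernel's
#'   peak latency `bp_lag_beats * mean_rri_ms / 1000` s.
#' @return Numeric deflection, same length as `t_rel`. Tends to 0 as
#'   `|t_rel|` grows.
#' @export
sigh_response_kernel <- function(t_rel, kernel, which = c("rri", "ptt", "bp"),
                                 mean_rri_ms = 800) {
  if (!inherits(kernel, "sigh_kernel")) stop_config("kernel must be a sigh_kernel")
  which <- match.arg(which)
  switch(which,
    rri = -kernel$rri_dip_amplitude *
      exp(-t_rel^2 / (2 * kernel$rri_dip_width^2)),
    ptt = kernel$ptt_rise_amplitude *
      exp(-t_rel^2 / (2 * kernel$ptt_rise_width^2)),
    bp = {
      tp <- kernel$bp_lag_beats * mean_rri_ms / 1000
      alpha <- tp / kernel$bp_recovery_tau
      out <- numeric(length(t_rel))
      pos <- t_rel > 0
      # gamma-shaped pulse normalized to peak at t_rel = tp with height 1
      out[pos] <- (t_rel[pos] / tp)^alpha *
        exp(alpha - t_rel[pos] / kernel$bp_recovery_tau)
      kernel$bp_rise_amplitude * out
    })
}
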