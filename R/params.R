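#' Subject-level simulation parameters
#'
#' Physiological parameters of one simulated participant. Defaults are sex
#' specific and chosen so that a default cohort approximates the baseline
#' cardiovascular profile of healthy young adults (females: faster heart
#' rate, lower low-frequency HRV amplitude, lower pulse-transit-time
#' dispersion than males).
#'
#' Task modulation: `response_gain` scales all per-sigh kernel amplitudes
#' (males respond more strongly by default); `short_rsa_mult` attenuates the
#' respiratory sinus arrhythmia gain during the short-interval task (vagal
#' withdrawal under the heavier load, stronger in females);
#' `short_map_gain_mmhg` raises the pressure baseline during the
#' short-interval task (stroke-volume-driven MAP rise).
#'
#' @param sex `"M"` or `"F"`.
#' @param mean_rri Mean R-to-R interval, ms (600--1200).
#' @param rsa_gain Respiratory sinus arrhythmia amplitude on RRI, ms.
#' @param rsa_delay Delay from respiration peak to the RRI peak (heart-rate
#'   trough), s.
#' @param lf_osc_amplitude Amplitude of the ~0.1 Hz (Mayer-wave) RRI
#'   oscillation, ms.
#' @param lf_osc_freq Frequency of that oscillation, Hz.
#' @param eupneic_rate Resting breathing rate, breaths/min (8--24).
#' @param baseline_sbp,baseline_dbp Systolic/diastolic pressure, mmHg.
#' @param baseline_ptt Mean pulse transit time, ms (120--350).
#' @param arm_length Distance between pulse measurement sites, m.
#' @param kernel A [sigh_kernel()]; amplitudes are multiplied by
#'   `response_gain`.
#' @param response_gain Subject-specific multiplier on sigh kernel amplitudes.
#' @param short_rsa_mult Multiplier on `rsa_gain` during the short-interval
#'   task (1 = no vagal withdrawal).
#' @param short_map_gain_mmhg Additive pressure offset during the
#'   short-interval task, mmHg.
#' @param sbp_noise_task_mult Multiplier on the per-beat systolic noise during
#'   both sighing tasks (the mechanical cost of producing each sigh, assumed
#'   the same at either pacing; drives the high-frequency blood-pressure
#'   variability response equally in the two sighing tasks).
#' @param ptt_noise_task_mult Per-task multipliers (baseline, long, short) on
#'   the vasomotor PTT noise; the increment above 1 is scaled by
#'   `response_gain`, so stronger responders show larger pulse-transit-time
#'   variability increases under load.
#' @param rri_task_sd,bp_task_sd,ptt_task_sd Between-task physiological state
#'   jitter SDs (one additive draw per task segment): ms on mean RRI, mmHg on
#'   the pressure baseline, ms on mean PTT. These give the mixed models
#'   realistic subject-by-task residual variance.
#' @param gain_task_sd Log-scale SD of a per-task multiplier on the RSA and
#'   Mayer-wave amplitudes.
#' @param lf_sbp_amplitude Amplitude of the Mayer-wave oscillation rendered on
#'   systolic pressure, mmHg.
#' @param resp_sbp_gain Mechanical respiratory coupling on systolic pressure,
#'   mmHg per unit respiration.
#' @param rri_noise_sd Band-limited RRI noise SD, ms.
#' @param ptt_noise_sd Per-beat PTT noise SD, ms (the main driver of
#'   pulse-transit-time variability).
#' @param sbp_noise_sd Per-beat systolic pressure noise SD, mmHg.
#' @param ecg_noise_sd ECG channel additive noise SD (R spike height = 1).
#' @param resp_noise_sd Respiration channel additive noise SD (eupneic
#'   amplitude = 1).
#'
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(sex = c("F", "M"),
                           mean_rri = if (sex == "M") 861 else 786,
                           rsa_gain = 40,
                           rsa_delay = 0.8,
                           lf_osc_amplitude = if (sex == "M") 18 else 13,
                           lf_osc_freq = 0.1,
                           eupneic_rate = 15,
                           baseline_sbp = if (sex == "M") 116 else 113,
                           baseline_dbp = if (sex == "M") 70 else 68,
                           baseline_ptt = 230,
                           arm_length = 0.65,
                           kernel = sigh_kernel(),
                           response_gain = if (sex == "M") 1.2 else 0.85,
                           short_rsa_mult = if (sex == "M") 0.8 else 0.6,
                           short_map_gain_mmhg = 3,
                           sbp_noise_task_mult = if (sex == "M") 2.2 else 1.8,
                           ptt_noise_task_mult = c(1, 1.12, 1.28),
                           rri_task_sd = 12,
                           bp_task_sd = 2,
                           ptt_task_sd = 6,
                           gain_task_sd = 0.12,
                           lf_sbp_amplitude = if (sex == "M") 2.0 else 1.4,
                           resp_sbp_gain = 1.5,
                           rri_noise_sd = 8,
                           ptt_noise_sd = if (sex == "M") 34 else 29,
                           sbp_noise_sd = 1.5,
                           ecg_noise_sd = 0.02,
                           resp_noise_sd = 0.05) {
  sex <- match.arg(sex)
  if (!is.finite(mean_rri) || mean_rri < 600 || mean_rri > 1200)
    stop_config("mean_rri must lie in [600, 1200] ms")
  if (eupneic_rate < 8 || eupneic_rate > 24)
    stop_config("eupneic_rate must lie in [8, 24] breaths/min")
  if (baseline_ptt < 120 || baseline_ptt > 350)
    stop_config("baseline_ptt must lie in [120, 350] ms")
  sds <- c(rri_noise_sd, ptt_noise_sd, sbp_noise_sd, ecg_noise_sd,
           resp_noise_sd, rri_task_sd, bp_task_sd, ptt_task_sd, gain_task_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop_config("noise SDs must be non-negative")
  if (length(ptt_noise_task_mult) != 3L || any(ptt_noise_task_mult <= 0))
    stop_config("ptt_noise_task_mult must be three positive multipliers")
  if (baseline_dbp >= baseline_sbp)
    stop_config("baseline_dbp must be below baseline_sbp")
  if (arm_length <= 0) stop_config("arm_length must be positive")
  if (rsa_delay < 0) stop_config("rsa_delay must be non-negative")
  if (!inherits(kernel, "sigh_kernel")) stop_config("kernel must be a sigh_kernel")

  structure(list(sex = sex, mean_rri = mean_rri, rsa_gain = rsa_gain,
                 rsa_delay = rsa_delay, lf_osc_amplitude = lf_osc_amplitude,
                 lf_osc_freq = lf_osc_freq, eupneic_rate = eupneic_rate,
                 baseline_sbp = baseline_sbp, baseline_dbp = baseline_dbp,
                 baseline_ptt = baseline_ptt, arm_length = arm_length,
                 kernel = kernel, response_gain = response_gain,
                 short_rsa_mult = short_rsa_mult,
                 short_map_gain_mmhg = short_map_gain_mmhg,
                 sbp_noise_task_mult = sbp_noise_task_mult,
                 ptt_noise_task_mult = ptt_noise_task_mult,
                 rri_task_sd = rri_task_sd, bp_task_sd = bp_task_sd,
                 ptt_task_sd = ptt_task_sd, gain_task_sd = gain_task_sd,
                 lf_sbp_amplitude = lf_sbp_amplitude,
                 resp_sbp_gain = resp_sbp_gain,
                 rri_noise_sd = rri_noise_sd, ptt_noise_sd = ptt_noise_sd,
                 sbp_noise_sd = sbp_noise_sd, ecg_noise_sd = ecg_noise_sd,
                 resp_noise_sd = resp_noise_sd),
            class = "subject_params")
}

#' Between-subject parameter dispersions for cohort simulation
#'
#' Standard deviations (and clipping bounds) used by [simulate_cohort()] when
#' drawing per-subject parameters around the sex-specific means of
#' [subject_params()]. Dispersions reflect baseline cohort spread of healthy
#' young adults (heart rate SD ~9-11 bpm by sex, PTT variability SD ~17-19 ms).
#' Setting `scale = 0` collapses every distribution to its mean.
#'
#' @param scale Global multiplier on all dispersions (0 = identical subjects).
#' @return A named list of SDs, class `cohort_dispersions`.
#' @export
cohort_dispersions <- function(scale = 1) {
  if (!is.finite(scale) || scale < 0)
    stop_config("dispersion scale must be non-negative")
  structure(list(
    mean_rri = 110 * scale,
    rsa_gain = 12 * scale,
    rsa_delay = 0.2 * scale,
    lf_osc_amplitude = 5 * scale,
    lf_osc_freq = 0.01 * scale,
    eupneic_rate = 2 * scale,
    baseline_sbp = 9 * scale,
    baseline_dbp = 6 * scale,
    baseline_ptt = 20 * scale,
    arm_length = 0.05 * scale,
    response_gain = 0.2 * scale,
    ptt_noise_sd = if (scale > 0) c(M = 16, F = 14) * scale else c(M = 0, F = 0),
    scale = scale
  ), class = "cohort_dispersions")
}
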