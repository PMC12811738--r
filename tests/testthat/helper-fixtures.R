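# Shared fixtures, built in code. Expensive objects are memoized so several
# test files can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a deterministic subject: oscillations on, measurement noise off
noiseless_params <- function(sex = "M", ...) {
  subject_params(sex = sex, rri_noise_sd = 0, ptt_noise_sd = 0,
                 sbp_noise_sd = 0, ecg_noise_sd = 0, resp_noise_sd = 0,
                 rri_task_sd = 0, bp_task_sd = 0, ptt_task_sd = 0,
                 gain_task_sd = 0, ...)
}

# fully constant physiology: no oscillations, no sighs expressed, no noise
constant_params <- function(sex = "M", ...) {
  noiseless_params(sex = sex, rsa_gain = 0, lf_osc_amplitude = 0,
                   response_gain = 0, lf_sbp_amplitude = 0,
                   resp_sbp_gain = 0, short_map_gain_mmhg = 0,
                   sbp_noise_task_mult = 1, short_rsa_mult = 1, ...)
}

noiseless_recording <- function() {
  memo("noiseless_rec",
       simulate_participant(noiseless_params(), build_protocol(), seed = 3))
}

noiseless_processed <- function() {
  memo("noiseless_proc", process_recording(noiseless_recording()))
}

# small default cohort shared by spectral-signature style tests
small_cohort_spectra <- function() {
  memo("small_cohort", simulate_process_cohort(20, seed = 101,
                                               keep_spectra = TRUE))
}

# match detected beats to ground-truth beats by nearest time
match_beats <- function(detected, truth_times) {
  vapply(detected, function(x) which.min(abs(truth_times - x)), integer(1))
}
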