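# Round-trip file I/O: plain CSV channels + a JSON sidecar per subject.

#' Default run configuration
#'
#' All defaults equal the protocol's stated values: 30-s/15-s sigh intervals,
#' 300-s segments, 60-s gaps, 2-s cues, 10-Hz low-pass, 4-Hz resampling,
#' 60-s Welch windows with 50% overlap and 2048-point FFT, LF 0.04-0.15 Hz,
#' HF 0.15-0.4 Hz.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort size.
#' @param fraction_female Proportion female.
#' @return Named list of class `fivs_config`.
#' @export
default_config <- function(seed = 1, n_subjects = 250,
                           fraction_female = 0.65) {
  structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    fraction_female = fraction_female,
    fs = 250,
    protocol = list(long_interval_s = 30, short_interval_s = 15,
                    segment_s = 300, gap_s = 60, cue_s = 2),
    insert_calibration_gaps = FALSE,
    lowpass_hz = 10,
    resample_rate = 4,
    welch = list(window_s = 60, overlap = 0.5, nfft = 2048),
    bands = list(LF = c(0.04, 0.15), HF = c(0.15, 0.40)),
    artifact = list(abs_bounds = c(300, 2000), rel_tol = 0.3,
                    max_flag_frac = 0.2),
    model = list(map_covariates = "pwv_hr", alpha = 0.05)
  ), class = "fivs_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @param config A [default_config()]-shaped list.
#' @return `read_config()` returns a `fivs_config`; `write_config()` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- utils::modifyList(cfg, raw)
  class(cfg) <- "fivs_config"
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialization; stamped into every output file
#' manifest so that outputs from different configurations are detectable.
#'
#' @param config A configuration list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

params_to_list <- function(p) {
  out <- unclass(p)
  out$kernel <- unclass(out$kernel)
  out
}

params_from_list <- function(l) {
  l$kernel <- do.call(sigh_kernel, l$kernel)
  do.call(subject_params, l)
}

timeline_to_list <- function(tl) {
  list(long_interval_s = tl$long_interval_s,
       short_interval_s = tl$short_interval_s,
       segment_s = tl$segment_s, gap_s = tl$gap_s, cue_s = tl$cue_s)
}

#' Write a recording to a directory
#'
#' One multi-column CSV of the sampled channels (`time`, `ecg`, `bp`, `resp`),
#' a JSON sidecar (sampling rate, seed, protocol, subject parameters,
#' calibration gaps, RSA ground truth), and the ground-truth beat and breath
#' tables as CSV.
#'
#' @param rec A [simulate_participant()] recording.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_data("cannot create directory: ", dir)
  n <- length(rec$channels$ecg)
  ch <- data.table::data.table(time = (seq_len(n) - 1) / rec$fs,
                               ecg = rec$channels$ecg,
                               bp = rec$channels$bp,
                               resp = rec$channels$resp)
  data.table::fwrite(ch, file.path(dir, "channels.csv"))
  sidecar <- list(
    fs = rec$fs, seed = rec$seed, n_samples = n,
    calibration_gaps = rec$calibration_gaps,
    protocol = timeline_to_list(rec$timeline),
    params = params_to_list(rec$params),
    rsa_delay = rec$ground_truth$rsa_delay,
    inhalation_peaks = rec$ground_truth$inhalation_peaks
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  data.table::fwrite(rec$ground_truth$beats,
                     file.path(dir, "ground_truth_beats.csv"))
  data.table::fwrite(rec$ground_truth$breaths,
                     file.path(dir, "ground_truth_breaths.csv"))
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory containing `channels.csv` and `sidecar.json`.
#' @return A `fivs_recording`.
#' @export
read_recording <- function(dir) {
  side_path <- file.path(dir, "sidecar.json")
  chan_path <- file.path(dir, "channels.csv")
  if (!file.exists(side_path)) stop_data("missing sidecar: ", side_path)
  if (!file.exists(chan_path)) stop_data("missing channels: ", chan_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ch <- data.table::fread(chan_path)
  need <- c("time", "ecg", "bp", "resp")
  if (!all(need %in% names(ch)))
    stop_data("channels.csv must contain columns: ", paste(need, collapse = ", "))
  if (nrow(ch) != side$n_samples)
    stop_data("channel length does not match sidecar (", nrow(ch),
              " vs ", side$n_samples, ")")
  gaps <- as.data.frame(side$calibration_gaps)
  if (!nrow(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  timeline <- do.call(build_protocol, side$protocol)
  params <- params_from_list(side$params)
  gt <- list(rsa_delay = side$rsa_delay,
             inhalation_peaks = as.numeric(side$inhalation_peaks))
  bt_path <- file.path(dir, "ground_truth_beats.csv")
  if (file.exists(bt_path)) gt$beats <- as.data.frame(data.table::fread(bt_path))
  br_path <- file.path(dir, "ground_truth_breaths.csv")
  if (file.exists(br_path)) gt$breaths <- as.data.frame(data.table::fread(br_path))
  structure(list(channels = list(ecg = ch$ecg, bp = ch$bp, resp = ch$resp),
                 fs = side$fs, calibration_gaps = gaps, ground_truth = gt,
                 params = params, timeline = timeline, seed = side$seed),
            class = "fivs_recording")
}
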