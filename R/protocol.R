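#' Build a fixed-interval sighing protocol timeline
#'
#' Constructs the task timeline shared by all simulated channels: a baseline
#' segment with no sigh cues, a long-interval sighing segment, and a
#' short-interval sighing segment, separated by inter-task gaps. Cue times are
#' laid on a fixed grid from each sighing segment's start; a cue is kept only
#' if the full cue duration fits inside its segment.
#'
#' @param long_interval_s Seconds between sigh cues in the long-interval task
#'   (default 30).
#' @param short_interval_s Seconds between sigh cues in the short-interval task
#'   (default 15).
#' @param segment_s Duration of each task segment in seconds (default 300).
#' @param gap_s Inter-task gap in seconds (default 60).
#' @param cue_s Sigh cue duration in seconds (default 2): the window within
#'   which the participant inhales sharply and exhales.
#' @param first_cue_frac Offset of the first cue into its segment, as a
#'   fraction of the sigh interval (default 0.5, i.e. the cue grid is centred
#'   in the segment). Keeping sigh events away from the segment boundary also
#'   keeps them away from the tapered edges of the 60-s spectral analysis
#'   windows, which are laid from the segment start.
#'
#' @return An object of class `fivs_protocol`: a list with
#'   `segments` (data.frame: `label`, `start`, `end`, seconds from recording
#'   start), `cues` (data.frame: `time`, `duration`), and `gap_s`.
#' @examples
#' tl <- build_protocol()
#' table(cut(tl$cues$time, breaks = c(tl$segments$start, Inf)))
#' @export
build_protocol <- function(long_interval_s = 30, short_interval_s = 15,
                           segment_s = 300, gap_s = 60, cue_s = 2,
                           first_cue_frac = 0.5) {
  vals <- c(long_interval_s, short_interval_s, segment_s, cue_s)
  if (any(!is.finite(vals)) || any(vals <= 0) || !is.finite(gap_s) || gap_s < 0)
    stop_config("protocol durations must be positive (gap may be zero)")
  if (cue_s >= long_interval_s || cue_s >= short_interval_s)
    stop_config("cue duration must be shorter than the sigh interval")
  if (first_cue_frac < 0 || first_cue_frac >= 1)
    stop_config("first_cue_frac must lie in [0, 1)")

  labels <- c("baseline", "long_interval", "short_interval")
  starts <- c(0, segment_s + gap_s, 2 * (segment_s + gap_s))
  segments <- data.frame(label = labels, start = starts,
                         end = starts + segment_s,
                         stringsAsFactors = FALSE)

  cue_grid <- function(seg_start, interval) {
    first <- first_cue_frac * interval
    if (first > segment_s - cue_s) return(numeric(0))
    offs <- seq(first, segment_s - cue_s, by = interval)
    seg_start + offs
  }
  cues <- data.frame(
    time = c(cue_grid(starts[2], long_interval_s),
             cue_grid(starts[3], short_interval_s)),
    duration = cue_s
  )

  structure(list(segments = segments, cues = cues, gap_s = gap_s,
                 segment_s = segment_s,
                 long_interval_s = long_interval_s,
                 short_interval_s = short_interval_s,
                 cue_s = cue_s),
            class = "fivs_protocol")
}

#' Sigh cues falling inside one protocol segment
#'
#' @param timeline A `fivs_protocol`.
#' @param label Segment label (`"baseline"`, `"long_interval"`,
#'   `"short_interval"`).
#' @return Numeric vector of cue onset times (s). Empty for the baseline.
#' @export
segment_cues <- function(timeline, label) {
  seg <- timeline$segments[timeline$segments$label == label, ]
  if (nrow(seg) != 1L) stop_config("unknown segment label: ", label)
  t <- timeline$cues$time
  t[t >= seg$start & t < seg$end]
}

#' @export
print.fivs_protocol <- function(x, ...) {
  cat("Fixed-interval volitional sighing protocol\n")
  for (i in seq_len(nrow(x$segments))) {
    seg <- x$segments[i, ]
    n <- length(segment_cues(x, seg$label))
    cat(sprintf("  %-15s %5.0f-%5.0f s  %3d sigh cues\n",
                seg$label, seg$start, seg$end, n))
  }
  cat(sprintf("  inter-task gap %.0f s, cue duration %.1f s\n",
              x$gap_s, x$cue_s))
  invisible(x)
}

# error constructors -----------------------------------------------------

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("sighstress_config_error",
                                             "error", "condition")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("sighstress_data_error",
                                             "error", "condition")))
}

stop_infeasible <- function(...) {
  stop(errorCondition(paste0(...), class = c("sighstress_infeasible_error",
                                             "error", "condition")))
}

stop_quality <- function(...) {
  stop(errorCondition(paste0(...), class = c("sighstress_quality_error",
                                             "error", "condition")))
}
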