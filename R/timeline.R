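#' Trial timeline specification
#'
#' Describes the common time base of a reach-and-grasp trial: the video frame
#' period, the trial duration, and the two boundaries splitting the trial into
#' the reaching, early grasping and firm grasping phases. Defaults correspond
#' to 25 Hz video (40 ms frames) over a 4,480 ms trial, i.e. 112 frames, with
#' phase boundaries at 1,020 ms (object touch) and 1,604 ms (firm hold).
#'
#' All intervals in the package are half-open `[start, end)`: a frame belongs
#' to a window or phase when its start time `t` satisfies `start <= t < end`.
#' Under this convention the 0--320 ms window holds 8 frames and the
#' 0--160 ms window holds 4.
#'
#' @param frame_period Frame period in ms (default 40, i.e. 25 Hz).
#' @param trial_duration Trial duration in ms; must be an exact multiple of
#'   `frame_period` (default 4480).
#' @param phase_boundaries Numeric length-2, the start times (ms) of the early
#'   grasping and firm grasping phases (default `c(1020, 1604)`).
#' @return An object of class `timeline_spec`.
#' @examples
#' spec <- timeline_spec()
#' n_frames(spec)                 # 112
#' frames_in_window(spec, 0, 320) # frames 0..7
#' @export
timeline_spec <- function(frame_period = 40, trial_duration = 4480,
                          phase_boundaries = c(1020, 1604)) {
  stopifnot(is.numeric(frame_period), length(frame_period) == 1L,
            is.numeric(trial_duration), length(trial_duration) == 1L,
            is.numeric(phase_boundaries), length(phase_boundaries) == 2L)
  if (frame_period <= 0) stop("'frame_period' must be positive")
  if (trial_duration %% frame_period != 0)
    stop("'trial_duration' (", trial_duration,
         ") must be an exact multiple of 'frame_period' (", frame_period, ")")
  b1 <- phase_boundaries[1L]; b2 <- phase_boundaries[2L]
  if (!(0 < b1 && b1 < b2 && b2 < trial_duration))
    stop("phase boundaries must satisfy 0 < b1 < b2 < trial_duration; got ",
         b1, ", ", b2)
  structure(list(frame_period = frame_period,
                 trial_duration = trial_duration,
                 phase_boundaries = c(b1, b2)),
            class = "timeline_spec")
}

#' @export
print.timeline_spec <- function(x, ...) {
  cat("Trial timeline: ", x$trial_duration, " ms at ",
      1000 / x$frame_period, " Hz (", n_frames(x), " frames of ",
      x$frame_period, " ms)\n", sep = "")
  cat("Phases [ms): reaching [0,", x$phase_boundaries[1],
      "), early grasping [", x$phase_boundaries[1], ",",
      x$phase_boundaries[2], "), firm grasping [",
      x$phase_boundaries[2], ",", x$trial_duration, ")\n", sep = "")
  invisible(x)
}

#' Number of frames in a trial
#'
#' @param spec A [timeline_spec()].
#' @return Integer frame count (`trial_duration / frame_period`).
#' @export
n_frames <- function(spec) {
  stopifnot(inherits(spec, "timeline_spec"))
  as.integer(spec$trial_duration / spec$frame_period)
}

#' Frame start times of a trial
#'
#' @param spec A [timeline_spec()].
#' @return Numeric vector of frame start times in ms (frame k starts at
#'   `k * frame_period`, k = 0..n-1).
#' @export
frame_times <- function(spec) {
  stopifnot(inherits(spec, "timeline_spec"))
  seq(0, spec$trial_duration - spec$frame_period, by = spec$frame_period)
}

#' Frames covered by a half-open time window
#'
#' Returns the indices (0-based) of frames whose start time t satisfies
#' `start <= t < end`. Window bounds must be multiples of the frame period
#' and lie within the trial.
#'
#' @param spec A [timeline_spec()].
#' @param start,end Window bounds in ms, `0 <= start < end <= trial_duration`.
#' @return Integer vector of 0-based frame indices.
#' @examples
#' frames_in_window(timeline_spec(), 0, 320)  # 0..7 (8 frames)
#' frames_in_window(timeline_spec(), 0, 160)  # 0..3 (4 frames)
#' @export
frames_in_window <- function(spec, start, end) {
  stopifnot(inherits(spec, "timeline_spec"),
            is.numeric(start), length(start) == 1L,
            is.numeric(end), length(end) == 1L)
  if (start < 0) stop("window start ", start, " lies before the trial (< 0)")
  if (end > spec$trial_duration)
    stop("window end ", end, " lies beyond the trial (> ",
         spec$trial_duration, ")")
  if (start >= end) stop("window start (", start,
                         ") must be strictly before end (", end, ")")
  if (start %% spec$frame_period != 0)
    stop("window start ", start, " is not a multiple of the frame period")
  if (end %% spec$frame_period != 0)
    stop("window end ", end, " is not a multiple of the frame period")
  seq.int(start %/% spec$frame_period, end %/% spec$frame_period - 1L)
}

#' Grasp phase at a time point
#'
#' Maps a time (ms) to the phase containing it under the half-open convention:
#' reaching on `[0, b1)`, early grasping on `[b1, b2)`, firm grasping on
#' `[b2, trial_duration)`.
#'
#' @param spec A [timeline_spec()].
#' @param time Numeric vector of times in ms, each in `[0, trial_duration)`.
#' @return Factor with levels `reaching`, `early_grasping`, `firm_grasping`.
#' @examples
#' phase_of(timeline_spec(), c(0, 1020, 1604))
#' @export
phase_of <- function(spec, time) {
  stopifnot(inherits(spec, "timeline_spec"), is.numeric(time))
  if (any(time < 0 | time >= spec$trial_duration))
    stop("time out of range [0, ", spec$trial_duration, "): ",
         paste(time[time < 0 | time >= spec$trial_duration], collapse = ", "))
  lv <- c("reaching", "early_grasping", "firm_grasping")
  idx <- 1L + (time >= spec$phase_boundaries[1L]) +
    (time >= spec$phase_boundaries[2L])
  factor(lv[idx], levels = lv)
}

#' Trial count of a fully crossed cohort
#'
#' @param n_subjects,n_gestures,n_objects_per_gesture,n_repetitions Positive
#'   counts of the cohort's crossed factors.
#' @return The product, i.e. the number of trials.
#' @examples
#' cohort_size(30, 10, 3, 4)  # 3600
#' cohort_size(1, 10, 3, 4)   # 120 per subject
#' @export
cohort_size <- function(n_subjects, n_gestures, n_objects_per_gesture,
                        n_repetitions) {
  counts <- c(n_subjects, n_gestures, n_objects_per_gesture, n_repetitions)
  stopifnot(is.numeric(counts), length(counts) == 4L)
  if (any(counts <= 0) || any(counts != as.integer(counts)))
    stop("all cohort dimensions must be positive integers")
  as.integer(prod(counts))
}
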