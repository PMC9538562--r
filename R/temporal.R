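new_cohort_curve <- function(statistic, spec, time, numerator, denominator) {
  value <- ifelse(denominator > 0, numerator / denominator, NA_real_)
  structure(data.frame(frame = seq_along(time) - 1L,
                       time = time,
                       value = value,
                       numerator = numerator,
                       denominator = denominator),
            statistic = statistic, timeline = spec,
            class = c("cohort_curve", "data.frame"))
}

#' Valid-frame proportion at each time point
#'
#' For every frame time t, the fraction of trials whose frame at t is valid
#' (target object visible and detected). The denominator at every time point
#' is the number of trials in the cohort; numerator and denominator counts
#' are kept alongside the proportion.
#'
#' @param cohort A `grasp_cohort`.
#' @return A `cohort_curve` data.frame with columns `frame`, `time`, `value`,
#'   `numerator`, `denominator`.
#' @export
valid_proportion_curve <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  spec <- cohort_timeline(cohort)
  vis <- cohort[cohort$source == "vision", ]
  if (nrow(vis) == 0L) stop("empty cohort: no vision frames")
  ft <- frame_times(spec)
  n_trials <- nrow(unique(vis[c("subject", "gesture", "object",
                                "repetition")]))
  idx <- match(vis$time, ft)
  num <- tabulate(idx[vis$valid], length(ft))
  new_cohort_curve("valid_proportion", spec, ft, num,
                   rep(n_trials, length(ft)))
}

#' Classification accuracy at each time point
#'
#' For the vision sources, the value at frame time t is the fraction of
#' *valid* frames at t whose prediction matches the truth (the denominator
#' counts valid frames only); for the sEMG source the denominator is every
#' trial with a decision at t. Time points with an empty denominator get an
#' `NA` value — they are undefined, not zero.
#'
#' @param cohort A `grasp_cohort`.
#' @param source One of `"gesture_vision"`, `"object_vision"`, `"emg"`.
#' @return A `cohort_curve` data.frame.
#' @export
accuracy_curve <- function(cohort,
                           source = c("gesture_vision", "object_vision",
                                      "emg")) {
  stopifnot(is.data.frame(cohort))
  source <- match.arg(source)
  spec <- cohort_timeline(cohort)
  if (source == "emg") {
    x <- cohort[cohort$source == "emg", ]
    if (nrow(x) == 0L) stop("cohort has no sEMG rows")
    tt <- sort(unique(x$time))
    correct <- x$pred_gesture == x$true_gesture
    idx <- match(x$time, tt)
    num <- tabulate(idx[correct], length(tt))
    den <- tabulate(idx, length(tt))
    return(new_cohort_curve("emg_accuracy", spec, tt, num, den))
  }
  x <- cohort[cohort$source == "vision", ]
  if (nrow(x) == 0L) stop("cohort has no vision rows")
  correct <- if (source == "gesture_vision")
    x$pred_gesture == x$true_gesture
  else
    x$pred_object == x$object
  ft <- frame_times(spec)
  idx <- match(x$time, ft)
  ok <- !is.na(x$valid) & x$valid
  num <- tabulate(idx[ok & !is.na(correct) & correct], length(ft))
  den <- tabulate(idx[ok], length(ft))
  new_cohort_curve(paste0(source, "_accuracy"), spec, ft, num, den)
}

#' @export
print.cohort_curve <- function(x, ...) {
  cat("Cohort curve '", attr(x, "statistic"), "': ", nrow(x),
      " time points, value range ",
      paste(round(range(x$value, na.rm = TRUE), 3), collapse = "-"),
      if (anyNA(x$value)) paste0(" (", sum(is.na(x$value)),
                                 " undefined points)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.cohort_curve <- function(x, shade = NULL, ...) {
  spec <- attr(x, "timeline")
  graphics::plot(x$time, 100 * x$value, type = "l",
                 xlab = "time (ms)", ylab = paste(attr(x, "statistic"), "(%)"),
                 ylim = c(0, 100), ...)
  if (!is.null(spec))
    graphics::abline(v = spec$phase_boundaries, lty = 2, col = "grey40")
  if (!is.null(shade))
    graphics::rect(shade[1], 0, shade[2], 100,
                   col = grDevices::adjustcolor("steelblue", 0.2),
                   border = NA)
  invisible(x)
}

#' Find the vision sweet period
#'
#' Searches the anchored windows `[0, e)` for every frame boundary `e` and
#' scores each by the mean of the curve values over its frames. Returns the
#' highest-scoring window among those with at least `min_window_frames`
#' frames; score ties are broken toward the shorter window. All candidate
#' scores are kept in the result so the selection can be audited — e.g. a
#' shorter window that scored higher but fell below the minimum length.
#'
#' The minimum-length constraint (default 5) reflects that a plurality vote
#' over at most 4 frames is fragile: one misclassified frame caps its
#' confidence at 75%.
#'
#' @param curve A `cohort_curve` (normally the valid-proportion curve).
#' @param min_window_frames Smallest admissible window length in frames
#'   (default 5).
#' @return An object of class `sweet_period`: a list with `start`, `end`
#'   (ms), `score`, `frame_count`, and a `candidates` data.frame of all
#'   window scores.
#' @export
find_sweet_period <- function(curve, min_window_frames = 5) {
  stopifnot(is.data.frame(curve), nrow(curve) > 0)
  if (min_window_frames < 1) stop("'min_window_frames' must be >= 1")
  if (min_window_frames > nrow(curve))
    stop("'min_window_frames' (", min_window_frames,
         ") exceeds the trial length (", nrow(curve), " frames)")
  spec <- attr(curve, "timeline")
  period <- if (!is.null(spec)) spec$frame_period else diff(curve$time[1:2])
  v <- curve$value
  if (anyNA(v))
    stop("curve has undefined points; cannot score anchored windows")
  k <- seq_along(v)
  score <- cumsum(v) / k
  candidates <- data.frame(start = 0, end = k * period, frames = k,
                           score = score,
                           admissible = k >= min_window_frames)
  adm <- which(candidates$admissible)
  best <- adm[which.max(score[adm])]  # which.max takes the first = shortest
  structure(list(start = 0, end = candidates$end[best],
                 score = score[best], frame_count = k[best],
                 min_window_frames = min_window_frames,
                 candidates = candidates),
            class = "sweet_period")
}

#' @export
print.sweet_period <- function(x, ...) {
  cat("Sweet period [", x$start, ", ", x$end, ") ms: ", x$frame_count,
      " frames, mean score ", round(x$score, 4),
      " (windows anchored at 0 ms, length >= ", x$min_window_frames,
      " frames)\n", sep = "")
  top <- x$candidates[order(-x$candidates$score), ]
  cat("Top candidates:\n")
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}

#' Pooled accuracy over a time window
#'
#' Pools every (trial, time point) pair inside `[start, end)` — valid frames
#' for the vision sources, all decision points for sEMG — and returns the
#' fraction classified correctly, with the counts it was computed from.
#'
#' @param cohort A `grasp_cohort`.
#' @param source One of `"gesture_vision"`, `"object_vision"`, `"emg"`.
#' @param window Numeric length-2, `c(start, end)` in ms (half-open).
#' @return A list with `accuracy` (NA if no observation fell in the window),
#'   `correct` and `total` counts.
#' @export
window_mean_accuracy <- function(cohort,
                                 source = c("gesture_vision",
                                            "object_vision", "emg"),
                                 window) {
  stopifnot(is.data.frame(cohort), is.numeric(window),
            length(window) == 2L)
  source <- match.arg(source)
  spec <- cohort_timeline(cohort)
  if (window[1] < 0 || window[2] > spec$trial_duration ||
      window[1] >= window[2])
    stop("window must lie within the trial with start < end")
  if (source == "emg") {
    x <- cohort[cohort$source == "emg" & cohort$time >= window[1] &
                  cohort$time < window[2], ]
    correct <- x$pred_gesture == x$true_gesture
  } else {
    x <- cohort[cohort$source == "vision" & cohort$time >= window[1] &
                  cohort$time < window[2], ]
    x <- x[!is.na(x$valid) & x$valid, ]
    correct <- if (source == "gesture_vision")
      x$pred_gesture == x$true_gesture
    else x$pred_object == x$object
  }
  total <- nrow(x)
  if (total == 0L)
    return(list(accuracy = NA_real_, correct = 0L, total = 0L))
  list(accuracy = sum(correct) / total, correct = sum(correct),
       total = total)
}
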