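#' Plurality vote over a sequence of gesture decisions
#'
#' Tallies the votes and returns the winning label together with its vote
#' fraction, the decision's confidence. An empty vote sequence yields an
#' *absent* decision with confidence 0; ties between labels are broken
#' toward the lowest gesture ID, so the result is deterministic.
#'
#' @param votes Integer vector of gesture IDs (may be empty).
#' @return An object of class `vote_decision`: list with `label`,
#'   `confidence` (winning votes / votes cast), `votes_cast`, `present`.
#' @examples
#' plurality_vote(c(2L, 2L, 2L, 7L))  # label 2, confidence 0.75
#' plurality_vote(integer(0))         # absent
#' @export
plurality_vote <- function(votes) {
  votes <- votes[!is.na(votes)]
  n <- length(votes)
  if (n == 0L)
    return(structure(list(label = NA_integer_, confidence = 0,
                          votes_cast = 0L, present = FALSE),
                     class = "vote_decision"))
  counts <- table(votes)
  top <- max(counts)
  winners <- as.integer(names(counts)[counts == top])
  structure(list(label = min(winners), confidence = top / n,
                 votes_cast = n, present = TRUE),
            class = "vote_decision")
}

#' @export
print.vote_decision <- function(x, ...) {
  if (!x$present) cat("Vote decision: absent (no votes)\n")
  else cat("Vote decision: gesture ", x$label, " with confidence ",
           round(x$confidence, 4), " (", x$votes_cast, " votes)\n",
           sep = "")
  invisible(x)
}

#' Vision decision of one trial over a sweet period
#'
#' Plurality vote over the predicted gestures of the *valid* vision frames
#' inside the window. A trial with no valid frame in the window yields an
#' absent decision (confidence 0) — vision simply has nothing to say.
#'
#' @param trial Cohort rows of a single trial.
#' @param window Numeric `c(start, end)` in ms, or a `sweet_period`.
#' @return A `vote_decision`.
#' @export
vision_decision <- function(trial, window) {
  if (inherits(window, "sweet_period")) window <- c(window$start, window$end)
  v <- trial[trial$source == "vision" & trial$time >= window[1] &
               trial$time < window[2], ]
  plurality_vote(v$pred_gesture[!is.na(v$valid) & v$valid])
}

#' sEMG decision of one trial over the sEMG sweet period
#'
#' Plurality vote over every sEMG decision point inside the window (all sEMG
#' points are available by construction — muscles are always recorded). A
#' trial without any sEMG record in the window is malformed and raises an
#' error rather than returning an absent decision.
#'
#' @param trial Cohort rows of a single trial.
#' @param window Numeric `c(start, end)` in ms (default the 1,100--1,400 ms
#'   sEMG sweet period).
#' @return A `vote_decision`.
#' @export
emg_decision <- function(trial, window = c(1100, 1400)) {
  e <- trial[trial$source == "emg" & trial$time >= window[1] &
               trial$time < window[2], ]
  if (nrow(e) == 0L)
    stop("malformed trial: no sEMG decision points in [",
         window[1], ", ", window[2], ")")
  plurality_vote(e$pred_gesture)
}

#' Max-confidence fusion of a vision and an sEMG decision
#'
#' Picks the modality with the higher plurality-vote confidence. sEMG is the
#' default modality: vision wins only when present and *strictly* more
#' confident; an exact tie, or an absent vision decision, falls back to
#' sEMG.
#'
#' @param vision A `vote_decision` (may be absent).
#' @param emg A present `vote_decision`.
#' @return A list with `chosen_source` (`"vision"` or `"emg"`),
#'   `final_label`, and both confidences.
#' @examples
#' v <- plurality_vote(c(3L, 3L, 3L, 3L))       # confidence 1.00
#' e <- plurality_vote(c(5L, 5L, 5L, 5L, 5L, 5L, 1L))  # confidence 0.857
#' fuse(v, e)$chosen_source  # "vision"
#' @export
fuse <- function(vision, emg) {
  stopifnot(inherits(vision, "vote_decision"),
            inherits(emg, "vote_decision"))
  if (!emg$present)
    stop("sEMG decision is absent; sEMG is always available, so this trial ",
         "is malformed")
  use_vision <- vision$present && vision$confidence > emg$confidence
  list(chosen_source = if (use_vision) "vision" else "emg",
       final_label = if (use_vision) vision$label else emg$label,
       vision_confidence = if (vision$present) vision$confidence else 0,
       emg_confidence = emg$confidence)
}

#' Per-trial fusion outcomes over a cohort
#'
#' Computes, for every trial: the vision plurality decision over the vision
#' sweet period (valid frames only), the sEMG plurality decision over the
#' sEMG sweet period, and the max-confidence fused result.
#'
#' @param cohort A `grasp_cohort`.
#' @param vision_window Numeric `c(start, end)` ms or a `sweet_period`.
#' @param emg_window Numeric `c(start, end)` ms (default 1,100--1,400).
#' @return A data.frame of class `fusion_outcomes`, one row per trial:
#'   trial key, per-modality labels/confidences/vote counts, the chosen
#'   source, the fused label, and correctness flags for all three routes.
#' @export
fuse_cohort <- function(cohort, vision_window, emg_window = c(1100, 1400)) {
  stopifnot(is.data.frame(cohort))
  if (inherits(vision_window, "sweet_period"))
    vision_window <- c(vision_window$start, vision_window$end)
  id <- trial_id(cohort)
  keys <- cohort_trials(cohort)
  kid <- paste(keys$subject, keys$gesture, keys$object, keys$repetition,
               sep = "\r")

  vsel <- cohort$source == "vision" & cohort$time >= vision_window[1] &
    cohort$time < vision_window[2] & !is.na(cohort$valid) & cohort$valid
  vvotes <- split(cohort$pred_gesture[vsel], factor(id[vsel], levels = kid))
  esel <- cohort$source == "emg" & cohort$time >= emg_window[1] &
    cohort$time < emg_window[2]
  evotes <- split(cohort$pred_gesture[esel], factor(id[esel], levels = kid))

  n <- nrow(keys)
  out <- keys
  out$vision_label <- rep(NA_integer_, n)
  out$vision_confidence <- rep(0, n)
  out$vision_votes <- rep(0L, n)
  out$vision_present <- rep(FALSE, n)
  out$emg_label <- rep(NA_integer_, n)
  out$emg_confidence <- rep(NA_real_, n)
  out$emg_votes <- rep(0L, n)
  out$chosen_source <- rep(NA_character_, n)
  out$final_label <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- plurality_vote(vvotes[[i]])
    e <- plurality_vote(evotes[[i]])
    if (!e$present)
      stop("trial ", gsub("\r", "/", kid[i]),
           " has no sEMG decision points in the sEMG window")
    f <- fuse(v, e)
    out$vision_label[i] <- v$label
    out$vision_confidence[i] <- if (v$present) v$confidence else 0
    out$vision_votes[i] <- v$votes_cast
    out$vision_present[i] <- v$present
    out$emg_label[i] <- e$label
    out$emg_confidence[i] <- e$confidence
    out$emg_votes[i] <- e$votes_cast
    out$chosen_source[i] <- f$chosen_source
    out$final_label[i] <- f$final_label
  }
  out$vision_correct <- out$vision_present &
    out$vision_label == out$true_gesture
  out$emg_correct <- out$emg_label == out$true_gesture
  out$fused_correct <- out$final_label == out$true_gesture
  rownames(out) <- NULL
  class(out) <- c("fusion_outcomes", "data.frame")
  out
}

#' Upper bound on vision plurality confidence
#'
#' The best plurality-vote confidence a vision decision can reach when at
#' most `max_valid` of the window's frames are valid and at least
#' `min_errors` of the cast votes miss the winning label:
#' `(max_valid - min_errors) / max_valid`. With fewer than five valid frames
#' and a single misclassified frame the bound is 3/4 — the reason a short
#' window's vote is fragile and sEMG (typically above 75% confidence) takes
#' over.
#'
#' @param window_frames Number of frames in the window.
#' @param max_valid Maximum number of valid frames (votes cast),
#'   `0 < max_valid <= window_frames`.
#' @param min_errors Minimum number of votes not for the winner,
#'   `0 <= min_errors <= max_valid`.
#' @return The confidence bound, a proportion.
#' @examples
#' max_vision_confidence_bound(8, 4, 1)  # 0.75
#' @export
max_vision_confidence_bound <- function(window_frames, max_valid,
                                        min_errors) {
  stopifnot(is.numeric(window_frames), is.numeric(max_valid),
            is.numeric(min_errors))
  if (max_valid <= 0 || max_valid > window_frames)
    stop("need 0 < max_valid <= window_frames")
  if (min_errors < 0 || min_errors > max_valid)
    stop("need 0 <= min_errors <= max_valid")
  # confidence (n - e)/n increases in n and decreases in e, so the bound is
  # attained at n = max_valid votes with exactly min_errors misses
  (max_valid - min_errors) / max_valid
}
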