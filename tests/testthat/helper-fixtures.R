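# hand-built trials and cohorts, plus independent brute-force oracles

default_spec <- timeline_spec()
default_tax <- grasp_taxonomy()

# a single trial in cohort (long) format with fully specified streams
stub_trial <- function(subject = 1L, gesture = 1L, object = "Bottle",
                       repetition = 1L,
                       valid = rep(TRUE, 112),
                       pred_gesture = NULL,
                       pred_object = NULL,
                       emg_pred = NULL,
                       spec = default_spec) {
  nf <- n_frames(spec)
  tv <- frame_times(spec)
  stopifnot(length(valid) == nf)
  if (is.null(pred_gesture)) pred_gesture <- rep(gesture, nf)
  if (is.null(pred_object)) pred_object <- rep(object, nf)
  if (is.null(emg_pred)) emg_pred <- rep(gesture, nf)
  pg <- ifelse(valid, as.integer(pred_gesture), NA_integer_)
  po <- ifelse(valid, pred_object, NA_character_)
  data.frame(subject = as.integer(subject), gesture = as.integer(gesture),
             object = object, repetition = as.integer(repetition),
             source = rep(c("vision", "emg"), each = nf),
             time = c(tv, tv),
             valid = c(valid, rep(NA, nf)),
             pred_gesture = c(pg, as.integer(emg_pred)),
             pred_object = c(po, rep(NA_character_, nf)),
             true_gesture = as.integer(gesture),
             stringsAsFactors = FALSE)
}

stub_cohort <- function(..., spec = default_spec) {
  coh <- do.call(rbind, list(...))
  rownames(coh) <- NULL
  attr(coh, "timeline") <- spec
  class(coh) <- c("grasp_cohort", "data.frame")
  coh
}

# curve object from raw values (for window-search tests)
stub_curve <- function(values, period = 40, n = 900) {
  tt <- (seq_along(values) - 1) * period
  structure(data.frame(frame = seq_along(values) - 1L, time = tt,
                       value = values,
                       numerator = round(values * n), denominator = n),
            statistic = "valid_proportion",
            timeline = timeline_spec(period, period * length(values),
                                     c(period, 2 * period)),
            class = c("cohort_curve", "data.frame"))
}

# independent plurality-vote oracle: explicit tally loop, first-lowest wins
oracle_plurality <- function(votes) {
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return(list(label = NA, confidence = 0))
  labs <- sort(unique(votes))
  cnt <- vapply(labs, function(l) sum(votes == l), numeric(1))
  best <- labs[cnt == max(cnt)][1]
  list(label = best, confidence = max(cnt) / length(votes))
}

# independent anchored-window oracle: score every end by an explicit mean
oracle_sweet_period <- function(values, min_frames, period = 40) {
  best_k <- NA; best_s <- -Inf
  for (k in seq_along(values)) {
    if (k < min_frames) next
    s <- sum(values[1:k]) / k
    if (s > best_s) { best_s <- s; best_k <- k }  # strict: ties keep shorter
  }
  list(end = best_k * period, score = best_s, frames = best_k)
}
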