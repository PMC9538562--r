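#' Parameters of the synthetic cohort generator
#'
#' Bundles the knobs of the synthetic decision-stream generator, which
#' emulates the statistical structure of classifier outputs during natural
#' reach-and-grasp trials: an egocentric-vision stream whose frames are only
#' sometimes "valid" (target object visible and detectable), and a
#' myoelectric (sEMG) stream that emits a gesture decision at every time
#' point.
#'
#' The per-frame probability that a vision frame is valid follows a
#' continuous piecewise-linear curve: a rise from `baseline` at 0 ms to
#' `peak` at `peak_time` (the object is in view while the subject fixates it
#' before moving), a linear decline to `floor` at `decline_end` (the
#' advancing hand progressively occludes the object), and a constant `floor`
#' for the rest of the trial (firm grasp, object mostly covered). A per-trial
#' time jitter (uniform on +/- `jitter` ms) shifts the whole curve, modelling
#' subjects touching the object at different moments. Defaults are calibrated
#' so the cohort-average valid proportion over the 0--320 ms vision window is
#' about 53%.
#'
#' Among valid frames, the vision gesture and object predictions are correct
#' independently with probabilities `acc_gesture` and `acc_object`; errors
#' are uniform over the other labels unless a `gesture_confusion` matrix is
#' supplied. The sEMG stream is generated from a per-trial dominant label
#' that is the true gesture with probability `emg_accuracy`; each decision
#' point repeats that label with probability `emg_consistency` (else a
#' uniform other label). This reproduces the regime in which the sEMG
#' plurality-vote confidence is typically above 75% while its trial-level
#' accuracy sits near 85.5%: a real sEMG classifier that errs tends to err
#' consistently within a trial.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_repetitions Repetitions of every gesture-object condition per
#'   subject (default 4).
#' @param baseline,peak,floor Validity probabilities at trial start, at the
#'   peak, and during firm grasping; must satisfy
#'   `floor <= baseline <= peak` (defaults 0.41, 0.63, 0.08).
#' @param peak_time,decline_end Times (ms) of the validity peak and of the
#'   end of the decline to `floor` (defaults 160 and 1020).
#' @param jitter Half-width (ms) of the uniform per-trial time shift of the
#'   validity curve (default 120; 0 disables).
#' @param validity_persistence First-order carry-over probability of the
#'   validity flag between consecutive frames (default 0 = independent
#'   frames; when positive the marginal curve is tracked only approximately).
#' @param acc_gesture,acc_object Per-frame probabilities that a valid frame's
#'   gesture / object prediction is correct (defaults 0.92 and 0.97).
#' @param gesture_confusion Optional square confusion matrix (rows = true
#'   gesture, columns = predicted) whose off-diagonal rows weight the error
#'   labels; `NULL` (default) uses uniform errors.
#' @param emg_period sEMG decision period in ms (default 40).
#' @param emg_accuracy Probability that a trial's dominant sEMG label is the
#'   true gesture (default 0.855).
#' @param emg_consistency Probability that an sEMG decision point repeats the
#'   trial's dominant label (default 0.93).
#' @param timeline A [timeline_spec()].
#' @param taxonomy A [grasp_taxonomy()].
#' @param seed Default master seed used by [generate_cohort()] when none is
#'   given explicitly.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_subjects = 30, n_repetitions = 4,
                             baseline = 0.41, peak = 0.63, floor = 0.08,
                             peak_time = 160, decline_end = 1020,
                             jitter = 120, validity_persistence = 0,
                             acc_gesture = 0.92, acc_object = 0.97,
                             gesture_confusion = NULL,
                             emg_period = 40, emg_accuracy = 0.855,
                             emg_consistency = 0.93,
                             timeline = timeline_spec(),
                             taxonomy = grasp_taxonomy(),
                             seed = 1L) {
  stopifnot(inherits(timeline, "timeline_spec"),
            inherits(taxonomy, "grasp_taxonomy"))
  probs <- c(baseline = baseline, peak = peak, floor = floor,
             acc_gesture = acc_gesture, acc_object = acc_object,
             emg_accuracy = emg_accuracy, emg_consistency = emg_consistency,
             validity_persistence = validity_persistence)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities out of [0,1]: ",
         paste(names(probs)[bad], collapse = ", "))
  if (!(floor <= baseline && baseline <= peak))
    stop("validity curve needs floor <= baseline <= peak; got ",
         floor, " / ", baseline, " / ", peak)
  if (!(0 < peak_time && peak_time < decline_end &&
        decline_end <= timeline$trial_duration))
    stop("need 0 < peak_time < decline_end <= trial_duration")
  if (n_subjects < 1 || n_repetitions < 1)
    stop("cohort dimensions must be positive")
  if (emg_period <= 0) stop("'emg_period' must be positive")
  if (jitter < 0) stop("'jitter' must be non-negative")
  if (!is.null(gesture_confusion)) {
    g <- gesture_ids(taxonomy)
    if (!is.matrix(gesture_confusion) ||
        nrow(gesture_confusion) != length(g) ||
        ncol(gesture_confusion) != length(g) ||
        any(gesture_confusion < 0))
      stop("'gesture_confusion' must be a non-negative ",
           length(g), "x", length(g), " matrix")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_repetitions = as.integer(n_repetitions),
                 baseline = baseline, peak = peak, floor = floor,
                 peak_time = peak_time, decline_end = decline_end,
                 jitter = jitter,
                 validity_persistence = validity_persistence,
                 acc_gesture = acc_gesture, acc_object = acc_object,
                 gesture_confusion = gesture_confusion,
                 emg_period = emg_period, emg_accuracy = emg_accuracy,
                 emg_consistency = emg_consistency,
                 timeline = timeline, taxonomy = taxonomy,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic cohort generator\n")
  cat("  cohort: ", x$n_subjects, " subjects x ", nrow(x$taxonomy),
      " gesture-object pairs x ", x$n_repetitions, " repetitions = ",
      x$n_subjects * nrow(x$taxonomy) * x$n_repetitions, " trials\n",
      sep = "")
  cat("  validity curve: ", x$baseline, " -> ", x$peak, " @", x$peak_time,
      " ms -> ", x$floor, " @", x$decline_end, " ms; jitter +/-", x$jitter,
      " ms\n", sep = "")
  cat("  vision accuracy: gesture ", x$acc_gesture, ", object ",
      x$acc_object, " (among valid frames)\n", sep = "")
  cat("  sEMG: period ", x$emg_period, " ms, trial accuracy ",
      x$emg_accuracy, ", point consistency ", x$emg_consistency, "\n",
      sep = "")
  invisible(x)
}

#' Frame-validity probability curve
#'
#' The piecewise-linear probability that a vision frame at time `time` is
#' valid, before per-trial jitter: linear rise from `baseline` to `peak`
#' over `[0, peak_time]`, linear decline from `peak` to `floor` over
#' `[peak_time, decline_end]`, constant `floor` afterwards. Times are clamped
#' to the trial interval, so the function is total.
#'
#' @param params A [generator_params()].
#' @param time Numeric vector of times in ms.
#' @return Probabilities in `[0, 1]`, one per time.
#' @export
validity_probability <- function(params, time) {
  stopifnot(inherits(params, "generator_params"), is.numeric(time))
  t <- pmin(pmax(time, 0), params$timeline$trial_duration)
  p <- ifelse(t <= params$peak_time,
              params$baseline +
                (params$peak - params$baseline) * t / params$peak_time,
              ifelse(t <= params$decline_end,
                     params$peak - (params$peak - params$floor) *
                       (t - params$peak_time) /
                       (params$decline_end - params$peak_time),
                     params$floor))
  unname(p)
}

#' Expected per-frame validity marginal under jitter
#'
#' The population probability that a frame at time `t` is valid equals the
#' average of [validity_probability()] over the uniform per-trial jitter.
#' This is the curve the empirical valid-frame proportion converges to; with
#' `jitter = 0` it coincides with [validity_probability()].
#'
#' @param params A [generator_params()].
#' @param times Times (ms) at which to evaluate; defaults to the frame start
#'   times of the params' timeline.
#' @param n_grid Number of jitter quadrature points (default 481).
#' @return Numeric vector of probabilities, one per time.
#' @export
expected_validity_curve <- function(params, times = NULL, n_grid = 481) {
  stopifnot(inherits(params, "generator_params"))
  if (is.null(times)) times <- frame_times(params$timeline)
  if (params$jitter == 0) return(validity_probability(params, times))
  js <- seq(-params$jitter, params$jitter, length.out = n_grid)
  vapply(times,
         function(t) mean(validity_probability(params, t - js)),
         numeric(1))
}

# Stable per-trial seed: distinct trials of one cohort get distinct streams,
# and the same (seed, key) always reproduces the same trial.
trial_seed <- function(seed, subject, pair_index, repetition) {
  code <- ((subject - 1) * 64 + pair_index) * 8 + repetition
  as.integer((as.numeric(seed) + 1000003 * code) %% 2147483647)
}

draw_labels <- function(n, true_label, labels, p_correct, confusion_row = NULL) {
  out <- rep(true_label, n)
  wrong <- runif(n) >= p_correct
  nw <- sum(wrong)
  if (nw > 0) {
    others <- labels[labels != true_label]
    if (is.null(confusion_row)) {
      out[wrong] <- others[sample.int(length(others), nw, replace = TRUE)]
    } else {
      w <- confusion_row[labels != true_label]
      if (sum(w) <= 0) w <- rep(1, length(others))
      out[wrong] <- others[sample.int(length(others), nw, replace = TRUE,
                                      prob = w)]
    }
  }
  out
}

#' Generate one synthetic grasp trial
#'
#' Draws the vision and sEMG decision streams of a single trial from the
#' generative model described in [generator_params()]. The trial's random
#' stream is derived deterministically from the master seed and the trial
#' key, so a single trial can be regenerated in isolation and cohorts are
#' reproducible regardless of generation order.
#'
#' @param params A [generator_params()].
#' @param subject Subject number (1-based).
#' @param gesture True gesture ID (must appear in the taxonomy).
#' @param object Object name (must pair with `gesture` in the taxonomy).
#' @param repetition Repetition number (1-based).
#' @param seed Master seed (default `params$seed`).
#' @return A data.frame in cohort (long) format: one row per vision frame and
#'   per sEMG decision point. See [generate_cohort()] for the columns.
#' @export
generate_trial <- function(params, subject, gesture, object, repetition,
                           seed = params$seed) {
  stopifnot(inherits(params, "generator_params"))
  cols <- gen_trial_cols(params, subject, gesture, object, repetition, seed)
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(df, "timeline") <- params$timeline
  df
}

# column vectors of one trial; kept as a list so cohort assembly can
# concatenate columns instead of rbind-ing thousands of data.frames
gen_trial_cols <- function(params, subject, gesture, object, repetition,
                           seed) {
  tax <- params$taxonomy
  pair <- which(tax$gesture_id == gesture & tax$object == object)
  if (length(pair) != 1L)
    stop("(gesture ", gesture, ", object '", object,
         "') is not a taxonomy pair")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(trial_seed(seed, subject, pair, repetition))
  spec <- params$timeline
  gl <- gesture_ids(tax)
  ol <- object_names(tax)
  tv <- frame_times(spec)
  nf <- length(tv)

  jit <- if (params$jitter > 0) runif(1, -params$jitter, params$jitter) else 0
  pv <- validity_probability(params, tv - jit)
  valid <- runif(nf) < pv
  if (params$validity_persistence > 0 && nf > 1) {
    keep <- runif(nf) < params$validity_persistence
    for (k in 2:nf) if (keep[k]) valid[k] <- valid[k - 1]
  }
  nv <- sum(valid)
  pg <- rep(NA_integer_, nf)
  po <- rep(NA_character_, nf)
  if (nv > 0) {
    conf_row <- if (!is.null(params$gesture_confusion))
      params$gesture_confusion[match(gesture, gl), ] else NULL
    pg[valid] <- draw_labels(nv, gesture, gl, params$acc_gesture, conf_row)
    po[valid] <- draw_labels(nv, object, ol, params$acc_object)
  }

  te <- seq(0, spec$trial_duration - params$emg_period,
            by = params$emg_period)
  ne <- length(te)
  dominant <- draw_labels(1, gesture, gl, params$emg_accuracy)
  pe <- draw_labels(ne, dominant, gl, params$emg_consistency)

  n <- nf + ne
  list(subject = rep(as.integer(subject), n),
       gesture = rep(as.integer(gesture), n),
       object = rep(object, n),
       repetition = rep(as.integer(repetition), n),
       source = rep(c("vision", "emg"), c(nf, ne)),
       time = c(tv, te),
       valid = c(valid, rep(NA, ne)),
       pred_gesture = c(pg, as.integer(pe)),
       pred_object = c(po, rep(NA_character_, ne)),
       true_gesture = rep(as.integer(gesture), n))
}

#' Generate a synthetic cohort of grasp trials
#'
#' Produces one trial per (subject, gesture-object pair, repetition) over the
#' full taxonomy: under the defaults, 30 subjects x 30 pairs x 4 repetitions
#' = 3,600 trials, each with 112 vision frames and 112 sEMG decision points.
#'
#' The result is a long-format data.frame of class `grasp_cohort` with
#' columns `subject`, `gesture`, `object`, `repetition`, `source`
#' (`"vision"` or `"emg"`), `time` (ms), `valid` (logical; `NA` on sEMG
#' rows), `pred_gesture` (integer; `NA` on invalid vision frames),
#' `pred_object` (character; vision only), and `true_gesture`. The timeline
#' is carried in the `"timeline"` attribute.
#'
#' @param params A [generator_params()].
#' @param seed Master seed (default `params$seed`). Per-trial streams are
#'   derived from it and the trial key, so the same seed always yields the
#'   same cohort.
#' @return A `grasp_cohort` data.frame.
#' @examples
#' \donttest{
#' coh <- generate_cohort(generator_params(n_subjects = 1), seed = 7)
#' length(unique(interaction(coh$subject, coh$gesture, coh$object,
#'                           coh$repetition)))  # 120 trials
#' }
#' @export
generate_cohort <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "generator_params"))
  tax <- params$taxonomy
  keys <- expand.grid(repetition = seq_len(params$n_repetitions),
                      pair = seq_len(nrow(tax)),
                      subject = seq_len(params$n_subjects))
  n_trial <- nrow(keys)
  pieces <- vector("list", n_trial)
  for (i in seq_len(n_trial)) {
    pieces[[i]] <- gen_trial_cols(params,
                                  subject = keys$subject[i],
                                  gesture = tax$gesture_id[keys$pair[i]],
                                  object = tax$object[keys$pair[i]],
                                  repetition = keys$repetition[i],
                                  seed = seed)
  }
  cols <- lapply(names(pieces[[1L]]), function(nm)
    unlist(lapply(pieces, `[[`, nm), use.names = FALSE))
  names(cols) <- names(pieces[[1L]])
  coh <- as.data.frame(cols, stringsAsFactors = FALSE)
  attr(coh, "timeline") <- params$timeline
  class(coh) <- c("grasp_cohort", "data.frame")
  coh
}

#' @export
print.grasp_cohort <- function(x, ...) {
  tk <- unique(x[x$source == "vision",
                 c("subject", "gesture", "object", "repetition")])
  cat("Grasp cohort: ", nrow(tk), " trials (",
      length(unique(tk$subject)), " subjects), ",
      sum(x$source == "vision"), " vision frames (",
      sum(x$valid, na.rm = TRUE), " valid), ",
      sum(x$source == "emg"), " sEMG decision points\n", sep = "")
  invisible(x)
}

# unique trial id column used internally for grouping
trial_id <- function(cohort)
  paste(cohort$subject, cohort$gesture, cohort$object, cohort$repetition,
        sep = "\r")

cohort_timeline <- function(cohort) {
  spec <- attr(cohort, "timeline")
  if (is.null(spec)) timeline_spec() else spec
}

# one row per trial with its true gesture
cohort_trials <- function(cohort) {
  tk <- unique(cohort[cohort$source == "vision",
                      c("subject", "gesture", "object", "repetition",
                        "true_gesture")])
  rownames(tk) <- NULL
  tk
}
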