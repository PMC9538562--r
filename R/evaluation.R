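#' Leave-one-repetition-out folds
#'
#' Splits a cohort into one fold per repetition: fold r tests on every trial
#' with repetition r and trains on the rest. Every (subject, gesture, object)
#' condition must carry the same set of repetitions, so the test folds
#' partition the cohort.
#'
#' @param cohort A `grasp_cohort`.
#' @param n_repetitions Expected number of repetitions (default 4).
#' @return A list with one element per repetition, each a list holding
#'   `repetition`, `train` and `test` cohort subsets.
#' @export
loro_folds <- function(cohort, n_repetitions = 4) {
  stopifnot(is.data.frame(cohort))
  keys <- cohort_trials(cohort)
  reps <- sort(unique(keys$repetition))
  if (length(reps) != n_repetitions)
    stop("cohort has repetitions {", paste(reps, collapse = ","),
         "}; expected ", n_repetitions)
  cond <- paste(keys$subject, keys$gesture, keys$object, sep = "\r")
  per_cond <- split(keys$repetition, cond)
  ok <- vapply(per_cond, function(r)
    identical(sort(r), as.numeric(reps)) || identical(sort(r), reps),
    logical(1))
  if (!all(ok))
    stop("condition ", gsub("\r", "/", names(per_cond)[which(!ok)[1L]]),
         " lacks some repetitions; every (subject, gesture, object) must ",
         "have all ", n_repetitions)
  spec <- cohort_timeline(cohort)
  lapply(reps, function(r) {
    test <- cohort[cohort$repetition == r, , drop = FALSE]
    train <- cohort[cohort$repetition != r, , drop = FALSE]
    for (part in c("test", "train")) {
      x <- get(part)
      attr(x, "timeline") <- spec
      class(x) <- c("grasp_cohort", "data.frame")
      assign(part, x)
    }
    list(repetition = r, train = train, test = test)
  })
}

#' Accuracies of one test fold
#'
#' Scores a test fold under three routes: sEMG-only (the sEMG sweet-period
#' plurality label), vision-only (the vision sweet-period plurality label,
#' scored among trials where a vision decision exists), and the
#' max-confidence integration of the two. For vision, both denominators are
#' reported: `vision_only` over trials with a present vision decision, and
#' `vision_only_all` over all trials with absent decisions counted wrong.
#'
#' @param test_trials A `grasp_cohort` subset (one fold's test trials).
#' @param vision_window Numeric `c(start, end)` ms or a `sweet_period`.
#' @param emg_window Numeric `c(start, end)` ms.
#' @return A list of accuracies plus counts and the per-trial
#'   `fusion_outcomes`.
#' @export
evaluate_fold <- function(test_trials, vision_window,
                          emg_window = c(1100, 1400)) {
  out <- fuse_cohort(test_trials, vision_window, emg_window)
  n <- nrow(out)
  if (n == 0L) stop("empty test set")
  n_present <- sum(out$vision_present)
  list(emg_only = mean(out$emg_correct),
       vision_only = if (n_present > 0)
         sum(out$vision_correct[out$vision_present]) / n_present
       else NA_real_,
       vision_only_all = sum(out$vision_correct & out$vision_present) / n,
       integrated = mean(out$fused_correct),
       n_trials = n,
       n_vision_present = n_present,
       outcomes = out)
}

#' Run the full synthetic sweet-period fusion experiment
#'
#' End-to-end driver: generate a synthetic cohort (or take one supplied),
#' split it by leave-one-repetition-out, find the vision sweet period on
#' each fold's *training* trials (or once on the whole cohort, per
#' `sweet_period_scope`), score the test trials under sEMG-only,
#' vision-only and integrated classification, and pool over folds. All
#' randomness flows from one master seed recorded in the report.
#'
#' @param config An `experiment_config` from [load_config()].
#' @param cohort Optional pre-built `grasp_cohort`; by default one is
#'   generated from the config.
#' @param seed Master seed override (default `config$seed`).
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `curves.csv`, `outcomes.csv` and `window_scores.csv` there.
#' @param quiet Suppress progress messages.
#' @param curves Also compute the three per-timepoint accuracy curves
#'   (default `TRUE`; the valid-proportion curve is always computed since
#'   the sweet-period search needs it).
#' @return An object of class `sweetfuse_experiment`.
#' @export
run_experiment <- function(config = load_config(quiet = TRUE), cohort = NULL,
                           seed = config$seed, out_dir = NULL,
                           quiet = FALSE, curves = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(cohort)) {
    say("generating synthetic cohort (seed ", seed, ") ...")
    params <- config_generator_params(config)
    cohort <- generate_cohort(params, seed = seed)
  }
  say("cohort: ", nrow(cohort_trials(cohort)), " trials")
  folds <- loro_folds(cohort, config$n_repetitions)
  emg_win <- config$emg_window

  full_curve <- valid_proportion_curve(cohort)
  cohort_sp <- find_sweet_period(full_curve, config$min_window_frames)
  fold_results <- lapply(folds, function(f) {
    sp <- if (identical(config$sweet_period_scope, "train"))
      find_sweet_period(valid_proportion_curve(f$train),
                        config$min_window_frames)
    else cohort_sp
    say("fold (test repetition ", f$repetition, "): sweet period [",
        sp$start, ", ", sp$end, ") ms")
    res <- evaluate_fold(f$test, sp, emg_win)
    res$repetition <- f$repetition
    res$sweet_period <- sp
    res
  })

  acc <- function(field) vapply(fold_results, `[[`, numeric(1), field)
  nt <- vapply(fold_results, `[[`, numeric(1), "n_trials")
  outcomes <- do.call(rbind, lapply(fold_results, function(r) {
    o <- r$outcomes
    o$test_repetition <- r$repetition
    o
  }))
  rownames(outcomes) <- NULL
  n_present <- sum(outcomes$vision_present)
  pooled <- list(
    emg_only = mean(outcomes$emg_correct),
    vision_only = if (n_present > 0)
      sum(outcomes$vision_correct[outcomes$vision_present]) / n_present
    else NA_real_,
    vision_only_all = sum(outcomes$vision_correct &
                            outcomes$vision_present) / nrow(outcomes),
    integrated = mean(outcomes$fused_correct),
    n_trials = nrow(outcomes),
    n_vision_present = n_present)

  report <- structure(list(
    seed = seed,
    config = config,
    folds = lapply(fold_results, function(r)
      r[c("repetition", "emg_only", "vision_only", "vision_only_all",
          "integrated", "n_trials", "n_vision_present")]),
    fold_sweet_periods = lapply(fold_results, `[[`, "sweet_period"),
    cohort_sweet_period = cohort_sp,
    pooled = pooled,
    outcomes = outcomes,
    curves = c(list(valid_proportion = full_curve),
               if (curves) list(
                 gesture_vision = accuracy_curve(cohort, "gesture_vision"),
                 object_vision = accuracy_curve(cohort, "object_vision"),
                 emg = accuracy_curve(cohort, "emg"))),
    elapsed = proc.time()[["elapsed"]] - t0),
    class = "sweetfuse_experiment")

  if (!is.null(out_dir)) write_experiment(report, out_dir)
  report
}

#' Write the experiment artefacts of a run
#'
#' @param report A `sweetfuse_experiment`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(report, out_dir) {
  stopifnot(inherits(report, "sweetfuse_experiment"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- do.call(rbind, lapply(names(report$curves), function(nm) {
    cc <- as.data.frame(report$curves[[nm]])
    cc$statistic <- nm
    cc
  }))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$outcomes),
                   file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(report$cohort_sweet_period$candidates,
                   file.path(out_dir, "window_scores.csv"),
                   row.names = FALSE)
  js <- list(seed = report$seed,
             config = unclass(report$config),
             pooled = report$pooled[c("emg_only", "vision_only",
                                      "vision_only_all", "integrated",
                                      "n_trials", "n_vision_present")],
             folds = report$folds,
             sweet_period = report$cohort_sweet_period[
               c("start", "end", "score", "frame_count")])
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sweetfuse_experiment <- function(x, ...) {
  cat("Sweet-period fusion experiment (seed ", x$seed, ")\n", sep = "")
  sp <- x$cohort_sweet_period
  cat("Vision sweet period: [", sp$start, ", ", sp$end, ") ms (",
      sp$frame_count, " frames, mean valid proportion ",
      round(sp$score, 3), ")\n", sep = "")
  cat("sEMG sweet period:   [", x$config$emg_window[1], ", ",
      x$config$emg_window[2], ") ms\n", sep = "")
  p <- x$pooled
  cat(sprintf("Pooled accuracy over %d trials (%d folds):\n", p$n_trials,
              length(x$folds)))
  cat(sprintf("  sEMG only        %6.2f%%\n", 100 * p$emg_only))
  cat(sprintf("  vision only      %6.2f%%  (among %d trials with a vision decision)\n",
              100 * p$vision_only, p$n_vision_present))
  cat(sprintf("  integrated       %6.2f%%\n", 100 * p$integrated))
  invisible(x)
}

#' @export
summary.sweetfuse_experiment <- function(object, ...) {
  print(object)
  cat("\nPer-fold accuracies:\n")
  f <- do.call(rbind, lapply(object$folds, function(r)
    data.frame(test_repetition = r$repetition,
               emg_only = r$emg_only, vision_only = r$vision_only,
               integrated = r$integrated, n_trials = r$n_trials)))
  print(f, row.names = FALSE, digits = 4)
  cat("\nModality chosen by fusion: ")
  print(table(object$outcomes$chosen_source))
  invisible(object)
}

#' @export
plot.sweetfuse_experiment <- function(x, ...) {
  if (is.null(x$curves$gesture_vision))
    stop("report was built with curves = FALSE; re-run with curves = TRUE")
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  sp <- x$cohort_sweet_period
  plot(x$curves$valid_proportion, shade = c(sp$start, sp$end),
       main = "Valid-frame proportion")
  cg <- x$curves$gesture_vision
  graphics::plot(cg$time, 100 * cg$value, type = "l", ylim = c(0, 100),
                 xlab = "time (ms)", ylab = "accuracy (%)",
                 main = "Per-timepoint accuracy (among valid frames)")
  co <- x$curves$object_vision
  graphics::lines(co$time, 100 * co$value, col = "steelblue")
  ce <- x$curves$emg
  graphics::lines(ce$time, 100 * ce$value, col = "firebrick")
  graphics::legend("bottomright", c("gesture (vision)", "object (vision)",
                                    "sEMG"),
                   col = c("black", "steelblue", "firebrick"), lty = 1,
                   bty = "n")
  invisible(x)
}
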