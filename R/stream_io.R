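#' Write a cohort of decision streams to CSV
#'
#' Serialises a `grasp_cohort` to a flat UTF-8 CSV, one row per vision frame
#' or sEMG decision point, in a deterministic order (sorted by subject,
#' gesture, object, repetition, source, time) so that writing the same cohort
#' twice produces byte-identical files. Missing predictions (invalid vision
#' frames) and the validity flag on sEMG rows are encoded as the explicit
#' sentinel `"."`, never as an empty cell, so an invalid frame can always be
#' told apart from a corrupt row.
#'
#' @param cohort A `grasp_cohort` data.frame (see [generate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()] for the inverse.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  cols <- c("subject", "gesture", "object", "repetition", "source", "time",
            "valid", "pred_gesture", "pred_object", "true_gesture")
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(cohort)[cols]
  x <- x[order(x$subject, x$gesture, x$object, x$repetition, x$source,
               x$time), , drop = FALSE]
  sent <- function(v) ifelse(is.na(v), ".", as.character(v))
  x$valid <- sent(ifelse(is.na(x$valid), NA_character_,
                         ifelse(x$valid, "true", "false")))
  x$pred_gesture <- sent(x$pred_gesture)
  x$pred_object <- sent(x$pred_object)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(x) > 0)
    writeLines(do.call(paste, c(unname(lapply(x, as.character)),
                                list(sep = ","))), con)
  invisible(path)
}

#' Read a cohort of decision streams from CSV
#'
#' Reads a file produced by [write_cohort()] (or an equivalent export of real
#' classifier outputs) and validates it against the timeline and taxonomy:
#' every gesture/object label must be known, every trial must carry exactly
#' one vision row per frame of the timeline, and a vision row is consistent
#' only when `valid=true` rows carry predictions and `valid=false` rows carry
#' the `"."` sentinel. Validation failures are reported with the offending
#' row numbers (counting the header as row 1).
#'
#' @param path CSV file path.
#' @param spec A [timeline_spec()] the trials must conform to.
#' @param taxonomy A [grasp_taxonomy()] the labels must come from.
#' @return A `grasp_cohort` data.frame.
#' @export
read_cohort <- function(path, spec = timeline_spec(),
                        taxonomy = grasp_taxonomy()) {
  stopifnot(inherits(spec, "timeline_spec"),
            inherits(taxonomy, "grasp_taxonomy"))
  if (!file.exists(path)) stop("no such cohort file: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  cols <- c("subject", "gesture", "object", "repetition", "source", "time",
            "valid", "pred_gesture", "pred_object", "true_gesture")
  if (!identical(names(x), cols))
    stop("cohort header must be: ", paste(cols, collapse = ","))
  rowno <- seq_len(nrow(x)) + 1L  # file row numbers, header = 1

  num <- function(col) suppressWarnings(as.numeric(x[[col]]))
  fail <- function(what, bad)
    stop(what, " at file row(s) ",
         paste(utils::head(rowno[bad], 10), collapse = ", "),
         if (sum(bad) > 10) " ...", call. = FALSE)

  for (col in c("subject", "gesture", "repetition", "time", "true_gesture")) {
    v <- num(col)
    if (anyNA(v)) fail(paste0("non-numeric '", col, "'"), is.na(v))
    x[[col]] <- v
  }
  bad <- !(x$source %in% c("vision", "emg"))
  if (any(bad)) fail("unknown source (must be vision/emg)", bad)

  gl <- gesture_ids(taxonomy); ol <- object_names(taxonomy)
  bad <- !(x$gesture %in% gl) | !(x$true_gesture %in% gl)
  if (any(bad)) fail("gesture ID not in taxonomy", bad)
  bad <- !(x$object %in% ol)
  if (any(bad)) fail("object not in taxonomy", bad)
  bad <- !(x$pred_gesture == "." |
             suppressWarnings(as.numeric(x$pred_gesture)) %in% gl)
  if (any(bad)) fail("predicted gesture not in taxonomy", bad)
  bad <- !(x$pred_object %in% c(".", ol))
  if (any(bad)) fail("predicted object not in taxonomy", bad)

  vis <- x$source == "vision"
  bad <- vis & !(x$valid %in% c("true", "false"))
  if (any(bad)) fail("vision row with valid flag not true/false", bad)
  bad <- !vis & x$valid != "."
  if (any(bad)) fail("sEMG row carrying a validity flag", bad)
  bad <- vis & x$valid == "true" &
    (x$pred_gesture == "." | x$pred_object == ".")
  if (any(bad)) fail("valid vision frame without predictions", bad)
  bad <- vis & x$valid == "false" &
    (x$pred_gesture != "." | x$pred_object != ".")
  if (any(bad)) fail("invalid vision frame carrying predictions", bad)
  bad <- !vis & x$pred_gesture == "."
  if (any(bad)) fail("sEMG row without a prediction", bad)
  bad <- x$time < 0 | x$time >= spec$trial_duration
  if (any(bad)) fail("time outside the trial", bad)

  id <- paste(x$subject, x$gesture, x$object, x$repetition, sep = "\r")
  ft <- frame_times(spec)
  vis_times <- split(x$time[vis], id[vis])
  ok <- vapply(vis_times, function(tt)
    length(tt) == length(ft) && all(sort(tt) == ft), logical(1))
  if (!all(ok)) {
    tid <- names(vis_times)[which(!ok)[1L]]
    k <- x[match(tid, id), ]
    stop("trial (subject ", k$subject, ", gesture ", k$gesture,
         ", object '", k$object, "', repetition ", k$repetition,
         ") has ", length(vis_times[[tid]]),
         " vision rows; expected one per frame (", length(ft), ")",
         call. = FALSE)
  }
  no_vis <- setdiff(unique(id), names(vis_times))
  if (length(no_vis))
    stop("trial without vision rows: ",
         gsub("\r", "/", no_vis[1L]), call. = FALSE)
  tg_ok <- vapply(split(x$true_gesture == x$gesture, id), all, logical(1))
  if (!all(tg_ok))
    stop("trial true_gesture inconsistent with its key for trial ",
         gsub("\r", "/", names(tg_ok)[which(!tg_ok)[1L]]), call. = FALSE)

  coh <- data.frame(subject = as.integer(x$subject),
                    gesture = as.integer(x$gesture),
                    object = x$object,
                    repetition = as.integer(x$repetition),
                    source = x$source,
                    time = x$time,
                    valid = ifelse(vis, x$valid == "true", NA),
                    pred_gesture = suppressWarnings(
                      as.integer(replace(x$pred_gesture,
                                         x$pred_gesture == ".", NA))),
                    pred_object = ifelse(x$pred_object == ".", NA_character_,
                                         x$pred_object),
                    true_gesture = as.integer(x$true_gesture),
                    stringsAsFactors = FALSE)
  attr(coh, "timeline") <- spec
  class(coh) <- c("grasp_cohort", "data.frame")
  coh
}

config_defaults <- function() {
  list(frame_period = 40,
       trial_duration = 4480,
       phase_boundaries = c(1020, 1604),
       emg_window = c(1100, 1400),
       min_window_frames = 5,
       sweet_period_scope = "train",
       n_subjects = 30,
       n_repetitions = 4,
       baseline = 0.41, peak = 0.63, floor = 0.08,
       peak_time = 160, decline_end = 1020, jitter = 120,
       validity_persistence = 0,
       acc_gesture = 0.92, acc_object = 0.97,
       emg_period = 40, emg_accuracy = 0.855, emg_consistency = 0.93,
       seed = 1L)
}

#' Load an experiment configuration
#'
#' Reads a YAML key-value file, fills every absent key with the package
#' default, and rejects unknown keys outright (a typo never silently falls
#' back to a default). An empty or missing-key file therefore yields the
#' study defaults: 40 ms frames over 4,480 ms, phase boundaries 1,020 /
#' 1,604 ms, sEMG sweet period 1,100--1,400 ms, and the calibrated generator
#' settings. The effective configuration is echoed via `message()`.
#'
#' @param path Path to a YAML file; `NULL` gives pure defaults.
#' @param quiet Suppress the configuration echo (default `FALSE`).
#' @return A named list of class `experiment_config`.
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "experiment_config"
  if (!quiet)
    message("configuration: ",
            paste(names(unclass(cfg)),
                  vapply(unclass(cfg), function(v)
                    paste(format(v), collapse = "/"), ""),
                  sep = "=", collapse = " "))
  cfg
}

#' Build generator parameters from a configuration
#'
#' @param config An `experiment_config` from [load_config()].
#' @param taxonomy A [grasp_taxonomy()].
#' @return A [generator_params()] object.
#' @export
config_generator_params <- function(config, taxonomy = grasp_taxonomy()) {
  stopifnot(inherits(config, "experiment_config"))
  generator_params(
    n_subjects = config$n_subjects, n_repetitions = config$n_repetitions,
    baseline = config$baseline, peak = config$peak, floor = config$floor,
    peak_time = config$peak_time, decline_end = config$decline_end,
    jitter = config$jitter,
    validity_persistence = config$validity_persistence,
    acc_gesture = config$acc_gesture, acc_object = config$acc_object,
    emg_period = config$emg_period, emg_accuracy = config$emg_accuracy,
    emg_consistency = config$emg_consistency,
    timeline = timeline_spec(config$frame_period, config$trial_duration,
                             config$phase_boundaries),
    taxonomy = taxonomy,
    seed = config$seed)
}
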