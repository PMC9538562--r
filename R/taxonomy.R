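#' Grasp gesture / object taxonomy
#'
#' Loads the taxonomy of 10 canonical grasp gestures and the 18 household
#' objects they act on, as a long table of (gesture_id, gesture_name, object)
#' pairs. Most gestures pair with three objects; the medium wrap has four and
#' the prismatic four-finger grasp two, for 30 gesture-object conditions in
#' total. The packaged table is used both by the synthetic cohort generator
#' and by the cohort reader, so predictions and ground truth can never refer
#' to labels the scorer does not know.
#'
#' @param path Optional path to a taxonomy CSV with columns
#'   `gesture_id,gesture_name,object`; defaults to the table shipped with the
#'   package.
#' @return A data.frame of class `grasp_taxonomy` with one row per
#'   (gesture, object) pair.
#' @examples
#' tax <- grasp_taxonomy()
#' length(unique(tax$gesture_id))  # 10
#' length(unique(tax$object))      # 18
#' @export
grasp_taxonomy <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "grasp_taxonomy.csv",
                        package = "sweetfuse", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gesture_id", "gesture_name", "object")
  if (!identical(names(tab), need))
    stop("taxonomy file must have columns ", paste(need, collapse = ", "))
  tab$gesture_id <- as.integer(tab$gesture_id)
  if (anyNA(tab$gesture_id) || any(tab$gesture_id < 1L))
    stop("gesture_id must be a positive integer")
  if (anyDuplicated(tab[c("gesture_id", "object")]))
    stop("duplicated (gesture_id, object) pair in taxonomy")
  nm <- unique(tab[c("gesture_id", "gesture_name")])
  if (anyDuplicated(nm$gesture_id))
    stop("a gesture_id maps to more than one gesture_name")
  class(tab) <- c("grasp_taxonomy", "data.frame")
  tab
}

#' @export
print.grasp_taxonomy <- function(x, ...) {
  cat("Grasp taxonomy: ", length(unique(x$gesture_id)), " gestures, ",
      length(unique(x$object)), " objects, ", nrow(x),
      " gesture-object pairs\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

gesture_ids <- function(taxonomy) sort(unique(taxonomy$gesture_id))

object_names <- function(taxonomy) sort(unique(taxonomy$object))

# objects paired with one gesture, in taxonomy order
objects_of <- function(taxonomy, gesture)
  taxonomy$object[taxonomy$gesture_id == gesture]
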