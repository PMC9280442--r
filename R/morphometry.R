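#' Euclidean length of an element from its two landmarks
#'
#' The length of a skeletal element is the straight-line (Euclidean)
#' distance in mm between its two landmarks, rounded half-to-even to two
#' decimal places. Rounding happens here, once: every downstream
#' statistic (percent asymmetry, outlier screens, both tests) consumes
#' the rounded value, which is why specimens can have exactly 0.00
#' percent asymmetry.
#'
#' @param p1,p2 numeric length-3 vectors (x, y, z) in mm.
#' @return Length in mm, rounded to 2 decimal places.
#' @examples
#' element_length(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
element_length <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  .check(length(p1) == 3L && length(p2) == 3L,
         "landmarks must be 3D points")
  .check(all(is.finite(p1)) && all(is.finite(p2)),
         "landmark coordinates must be finite")
  round2(sqrt(sum((p1 - p2)^2)))
}

#' Measure all elements of one specimen
#'
#' Turns a mapped landmark set into one bilateral measurement per
#' anatomical element. An element with only one measurable side is
#' emitted excluded with reason `missing_side` (asymmetry needs both
#' sides). If the specimen is flagged broken, every record is excluded
#' with reason `broken`. Output ordering is by element name, independent
#' of the ordering of landmarks in the source file.
#'
#' @param set a `specimen_landmarks` object from [map_landmarks()].
#' @return A measurements data frame (columns `taxon`, `specimen_id`,
#'   `element`, `left_length`, `right_length`, `excluded`,
#'   `exclusion_reason`), possibly empty (with a warning) when no element
#'   side is measurable.
#' @export
measure_specimen <- function(set) {
  .check(inherits(set, "specimen_landmarks"),
         "set must come from map_landmarks()")
  a <- set$assignments
  elements <- sort(unique(a$element))
  rows <- lapply(elements, function(el) {
    side_len <- vapply(.sides, function(s) {
      pts <- a[a$element == el & a$side == s, c("x", "y", "z")]
      if (nrow(pts) == 2L)
        element_length(unlist(pts[1L, ]), unlist(pts[2L, ]))
      else NA_real_
    }, 0)
    if (all(is.na(side_len))) return(NULL)  # no measurable side
    reason <- if (set$broken) "broken"
              else if (anyNA(side_len)) "missing_side"
              else "none"
    data.frame(taxon = set$taxon, specimen_id = set$specimen_id,
               element = el,
               left_length = side_len[["left"]],
               right_length = side_len[["right"]],
               excluded = reason != "none", exclusion_reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    warning("specimen '", set$specimen_id,
            "' has no measurable element side", call. = FALSE)
    return(.empty_measurements())
  }
  rownames(out) <- NULL
  out
}

#' Measure every .pp file in a directory
#'
#' Convenience wrapper composing [read_pp()], [map_landmarks()] and
#' [measure_specimen()] over a directory of picked-points files, one file
#' per specimen (specimen id = file name without extension). Per-specimen
#' metadata (taxon, broken flag) comes from an optional sidecar data
#' frame, since `.pp` files cannot express it.
#'
#' @param dir directory containing `.pp` files.
#' @param rules a [landmark_rules()] table.
#' @param metadata optional data frame with columns `specimen_id`,
#'   `taxon` and optionally `broken` (logical).
#' @return A measurements data frame covering all specimens.
#' @export
measure_pp_dir <- function(dir, rules = default_landmark_rules(),
                           metadata = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pp$", full.names = TRUE))
  .check(length(files) > 0L, paste0("no .pp files found in '", dir, "'"))
  meta_row <- function(id) {
    if (is.null(metadata)) return(list(taxon = "unknown", broken = FALSE))
    i <- match(id, metadata$specimen_id)
    if (is.na(i)) return(list(taxon = "unknown", broken = FALSE))
    list(taxon = as.character(metadata$taxon[i]),
         broken = isTRUE("broken" %in% names(metadata) &&
                           as.logical(metadata$broken[i])))
  }
  out <- lapply(files, function(f) {
    id <- sub("\\.pp$", "", basename(f))
    m <- meta_row(id)
    lm <- tryCatch(read_pp(f), error = function(e)
      stop("failed to read '", f, "': ", conditionMessage(e),
           call. = FALSE))
    measure_specimen(map_landmarks(lm, rules, specimen_id = id,
                                   taxon = m$taxon, broken = m$broken))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
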