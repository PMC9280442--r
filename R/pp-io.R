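#' Read a MeshLab picked-points (.pp) landmark file
#'
#' Parses the XML dialect MeshLab uses to export digitized landmarks: a
#' `PickedPoints` document whose `<point>` entries carry `x`, `y`, `z`,
#' `name` and `active` attributes. Unknown sibling elements (e.g.
#' `DocumentData`) and unknown attributes are tolerated and ignored, since
#' exporter versions vary. Coordinates are taken as millimetres with no
#' rescaling; no coordinate-system handedness is assumed because only
#' intra-specimen distances are ever used downstream.
#'
#' @param file path to a `.pp` file, or a single string containing the XML
#'   document itself.
#' @return A data frame of class `landmarks` with one row per point, in
#'   file order: columns `name` (character), `x`, `y`, `z` (numeric, mm)
#'   and `active` (logical; `active="0"` marks a point a digitizer
#'   deactivated rather than deleted).
#' @seealso [write_pp()], [map_landmarks()]
#' @examples
#' doc <- write_pp(data.frame(name = c("pelvis_L_ant", "pelvis_L_post"),
#'                            x = c(0, 3), y = c(0, 4), z = 0,
#'                            active = TRUE))
#' read_pp(doc)
#' @export
read_pp <- function(file) {
  xml <- tryCatch(xml2::read_xml(file),
                  error = function(e)
                    stop("malformed picked-points XML: ", conditionMessage(e),
                         call. = FALSE))
  pts <- xml2::xml_find_all(xml, ".//point")
  if (length(pts) == 0L) stop("no landmarks", call. = FALSE)
  get_coord <- function(node, attr, i) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v))
      stop(sprintf("point %d ('%s') lacks coordinate attribute '%s'",
                   i, xml2::xml_attr(node, "name"), attr), call. = FALSE)
    x <- suppressWarnings(as.numeric(v))
    if (!is.finite(x))
      stop(sprintf("point %d: attribute '%s' ('%s') is not a finite number",
                   i, attr, v), call. = FALSE)
    x
  }
  n <- length(pts)
  out <- data.frame(
    name   = vapply(pts, xml2::xml_attr, "", attr = "name"),
    x      = vapply(seq_len(n), function(i) get_coord(pts[[i]], "x", i), 0),
    y      = vapply(seq_len(n), function(i) get_coord(pts[[i]], "y", i), 0),
    z      = vapply(seq_len(n), function(i) get_coord(pts[[i]], "z", i), 0),
    stringsAsFactors = FALSE)
  act <- vapply(pts, xml2::xml_attr, "", attr = "active")
  out$active <- is.na(act) | act != "0"
  if (anyNA(out$name) || any(!nzchar(out$name)))
    stop("every point must carry a non-empty 'name' attribute",
         call. = FALSE)
  class(out) <- c("landmarks", "data.frame")
  out
}

#' Write landmarks as a MeshLab picked-points (.pp) document
#'
#' Inverse of [read_pp()]: emits a `PickedPoints` XML document that
#' round-trips exactly (names, coordinates to full double precision,
#' active flags).
#'
#' @param landmarks data frame with columns `name`, `x`, `y`, `z` and
#'   optionally `active` (default all `TRUE`). Must have at least one row.
#' @param file optional path; if supplied the document is written there.
#' @return The XML document as a single string (invisibly when `file` is
#'   given).
#' @export
write_pp <- function(landmarks, file = NULL) {
  .check(is.data.frame(landmarks) && nrow(landmarks) > 0L,
         "cannot write an empty landmark list")
  .check(all(c("name", "x", "y", "z") %in% names(landmarks)),
         "landmarks need columns name, x, y, z")
  .check(all(is.finite(landmarks$x) & is.finite(landmarks$y) &
             is.finite(landmarks$z)), "coordinates must be finite")
  .check(all(nzchar(landmarks$name)), "landmark names must be non-empty")
  active <- if ("active" %in% names(landmarks)) landmarks$active else TRUE
  active <- rep_len(as.logical(active), nrow(landmarks))
  # 17 significant digits round-trip IEEE doubles exactly
  num <- function(v) sub("e([+-])0?(\\d)", "e\\1\\2",
                         formatC(v, digits = 17, format = "g", width = -1))
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  pts <- sprintf(
    ' <point x="%s" y="%s" z="%s" active="%d" name="%s"/>',
    num(landmarks$x), num(landmarks$y), num(landmarks$z),
    as.integer(active), esc(landmarks$name))
  doc <- paste(c('<!DOCTYPE PickedPoints>',
                 '<PickedPoints>',
                 ' <DocumentData>',
                 '  <DateTime date="" time=""/>',
                 ' </DocumentData>',
                 pts,
                 '</PickedPoints>', ''), collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}
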