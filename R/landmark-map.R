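#' Landmark naming rules
#'
#' Landmark names inside `.pp` files are free text chosen by the
#' digitizer, so the mapping from names to anatomical
#' (element, side, role) triples is configuration, not convention.
#' A rule table has one row per rule: a regular expression `pattern`
#' (matched case-insensitively against the full landmark name) and the
#' `element`, `side` and `role` it resolves to. Every rule must resolve to
#' exactly one triple; landmark names matched by no rule are reported, not
#' silently dropped.
#'
#' `landmark_rules()` builds a rule table from vectors;
#' `default_landmark_rules()` returns the scheme the synthetic-landmark
#' writer uses (`pelvis_L_ant`, `femur_R_dist`, ...);
#' `read_landmark_rules()` reads a plain-text config file with one
#' whitespace- or comma-separated rule per line:
#' `pattern element side role` (lines starting `#` are comments).
#'
#' @param pattern character vector of anchored regular expressions.
#' @param element,side,role character vectors recycled against `pattern`;
#'   `side` must be `"left"` or `"right"`.
#' @return A data frame of class `landmark_rules`.
#' @examples
#' default_landmark_rules()
#' @export
landmark_rules <- function(pattern, element, side, role) {
  out <- data.frame(pattern = pattern, element = element,
                    side = side, role = role, stringsAsFactors = FALSE)
  .check(all(out$side %in% .sides), "side must be 'left' or 'right'")
  .check(!any(duplicated(out[c("element", "side", "role")])),
         "two rules resolve to the same (element, side, role) triple")
  class(out) <- c("landmark_rules", "data.frame")
  out
}

#' @rdname landmark_rules
#' @export
default_landmark_rules <- function() {
  g <- expand.grid(role = c("ant", "post", "prox", "dist"),
                   s = c("L", "R"),
                   element = c("pelvis", "femur"),
                   stringsAsFactors = FALSE)
  # pelvis uses anterior/posterior landmarks, femur proximal/distal
  g <- g[(g$element == "pelvis" & g$role %in% c("ant", "post")) |
         (g$element == "femur"  & g$role %in% c("prox", "dist")), ]
  landmark_rules(
    pattern = sprintf("^%s_%s_%s$", g$element, g$s, g$role),
    element = g$element,
    side    = ifelse(g$s == "L", "left", "right"),
    role    = c(ant = "anterior", post = "posterior",
                prox = "proximal", dist = "distal")[g$role])
}

#' @rdname landmark_rules
#' @param file path to a rule config file.
#' @export
read_landmark_rules <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  .check(length(lines) > 0L, "rule file contains no rules")
  parts <- strsplit(lines, "[,[:space:]]+")
  ok <- lengths(parts) == 4L
  .check(all(ok), paste0("malformed rule line(s): ",
                         paste(lines[!ok], collapse = "; ")))
  m <- do.call(rbind, parts)
  landmark_rules(m[, 1], m[, 2], m[, 3], m[, 4])
}

#' Assign landmarks to anatomical element sides
#'
#' Maps each active landmark of one specimen to an
#' (element, side, role) triple via a [landmark_rules()] table. Inactive
#' landmarks (`active = FALSE`) are skipped: digitizers deactivate
#' mistaken points rather than delete them. Two landmarks resolving to the
#' same triple is an error; names matched by no rule are collected in the
#' `unmatched` field. An element side is *measurable* when both of its
#' roles are assigned, which is what [measure_specimen()] requires to
#' compute a length.
#'
#' @param landmarks a `landmarks` data frame from [read_pp()].
#' @param rules a `landmark_rules` table.
#' @param specimen_id,taxon identifiers attached to the result.
#' @param broken logical; `TRUE` flags the specimen's skeleton as broken,
#'   which excludes all of its measurements downstream.
#' @return An object of class `specimen_landmarks`: a list with
#'   `specimen_id`, `taxon`, `broken`, `assignments` (data frame
#'   `element`, `side`, `role`, `name`, `x`, `y`, `z`) and `unmatched`
#'   (character vector of unassigned landmark names).
#' @export
map_landmarks <- function(landmarks, rules = default_landmark_rules(),
                          specimen_id, taxon = "unknown", broken = FALSE) {
  .check(inherits(rules, "landmark_rules") ||
           all(c("pattern", "element", "side", "role") %in% names(rules)),
         "rules must be a landmark_rules table")
  act <- landmarks[landmarks$active, , drop = FALSE]
  hits <- lapply(seq_len(nrow(act)), function(i) {
    m <- which(vapply(rules$pattern, grepl, NA, x = act$name[i],
                      ignore.case = TRUE, perl = TRUE))
    if (length(m) == 0L) return(NULL)
    cbind(rules[m[1L], c("element", "side", "role")],
          act[i, c("name", "x", "y", "z")], row.names = NULL)
  })
  unmatched <- act$name[vapply(hits, is.null, NA)]
  assignments <- do.call(rbind, hits)
  if (is.null(assignments))
    assignments <- data.frame(element = character(), side = character(),
                              role = character(), name = character(),
                              x = numeric(), y = numeric(), z = numeric(),
                              stringsAsFactors = FALSE)
  key <- paste(assignments$element, assignments$side, assignments$role)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("conflicting landmark assignment: two landmarks map to (",
         gsub(" ", ", ", d), ")", call. = FALSE)
  }
  es <- unique(assignments[c("element", "side")])
  measurable <- vapply(seq_len(nrow(es)), function(i)
    sum(assignments$element == es$element[i] &
        assignments$side == es$side[i]) == 2L, NA)
  if (!any(measurable))
    warning("specimen '", specimen_id,
            "' has no measurable element side", call. = FALSE)
  structure(list(specimen_id = specimen_id, taxon = taxon, broken = broken,
                 assignments = assignments, unmatched = unmatched),
            class = "specimen_landmarks")
}

#' @export
print.specimen_landmarks <- function(x, ...) {
  cat("Specimen '", x$specimen_id, "' (", x$taxon, ")",
      if (x$broken) " [broken]", "\n", sep = "")
  if (nrow(x$assignments)) print(x$assignments, row.names = FALSE)
  else cat("  (no assigned landmarks)\n")
  if (length(x$unmatched))
    cat("  unmatched landmark name(s):",
        paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}
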