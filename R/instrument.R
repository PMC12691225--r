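#' Load a pain-scale definition from JSON
#'
#' A scale definition is a versioned JSON document describing the instrument:
#' ordered parts, each holding ordered items, each item carrying the set of
#' point values an assessor may award it.  Sparse point sets (e.g. `{0, 2, 4}`
#' where intermediate grades do not exist on the printed form) are encoded
#' verbatim; scoring a value outside the set is rejected.  Part and total
#' maxima are always recomputed from the item definitions; maxima stored in
#' the document are treated as declarations and cross-checked, never trusted.
#'
#' @param path path to a scale-definition JSON file.
#' @return a `scale_definition` object: a list with `scale_id`, `version`,
#'   `parts` (each part a list with `part_id`, `name`, `items`, `part_max`)
#'   and `total_max`.
#' @seealso [bundled_scale()] for the packaged postpartum-mare instrument,
#'   [scale_maximum()] for skip-adjusted maxima, [write_scale()] to
#'   serialize a definition back to JSON.
#' @export
load_scale <- function(path) {
  if (!file.exists(path)) {
    stop_with("scale_io_error", "scale definition not found: %s", path)
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_scale_document(doc)
}

#' The bundled postpartum-mare pain scale
#'
#' Returns the eight-part composite pain scale for heavy mares after
#' delivery that ships with the package: stall observation (max 19),
#' facial expression / Horse Grimace Scale (12), clinical examination (4),
#' mammary-gland and torso palpation (3), peristalsis (1), hoof
#' examination (2, four hooves at 0.5 each), food test (2), and walking
#' traits (4) -- 47 points in total.
#'
#' @return a `scale_definition` with `total_max` 47.
#' @export
#' @examples
#' sc <- bundled_scale()
#' sc$total_max               # 47
#' scale_maximum(sc)          # 47
bundled_scale <- function() {
  load_scale(system.file("extdata", "postpartum_mare_scale_v1.json",
                         package = "marepain", mustWork = TRUE))
}

# Validate a parsed scale document and attach computed maxima.
validate_scale_document <- function(doc) {
  for (field in c("scale_id", "version", "parts")) {
    if (is.null(doc[[field]])) {
      stop_with("scale_validation_error", "scale document lacks '%s'", field)
    }
  }
  if (length(doc$parts) == 0L) {
    stop_with("scale_validation_error", "scale document has no parts")
  }
  parts <- lapply(doc$parts, validate_part)
  ids <- unlist(lapply(parts, function(p) {
    vapply(p$items, function(it) it$item_id, character(1))
  }))
  if (anyDuplicated(ids)) {
    stop_with("scale_validation_error", "duplicate item_id: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  total <- sum(vapply(parts, function(p) p$part_max, numeric(1)))
  if (!is.null(doc$total_max) && abs(doc$total_max - total) > 1e-9) {
    stop_with("scale_integrity_error",
              "declared total_max %s != computed %s", doc$total_max, total)
  }
  structure(
    list(scale_id = doc$scale_id, version = as.character(doc$version),
         parts = parts, total_max = total),
    class = "scale_definition"
  )
}

validate_part <- function(part) {
  if (is.null(part$part_id) || is.null(part$name) || length(part$items) == 0L) {
    stop_with("scale_validation_error",
              "each part needs part_id, name and at least one item")
  }
  items <- lapply(part$items, function(it) {
    if (is.null(it$item_id) || is.null(it$allowed_points)) {
      stop_with("scale_validation_error",
                "item in part %s lacks item_id or allowed_points", part$part_id)
    }
    pts <- as.numeric(unlist(it$allowed_points))
    if (length(pts) == 0L || any(pts < 0) || !all(is_half_step(pts))) {
      stop_with("scale_validation_error",
                "item '%s': allowed_points must be non-negative multiples of 0.5",
                it$item_id)
    }
    if (is.unsorted(pts, strictly = TRUE)) {
      stop_with("scale_validation_error",
                "item '%s': allowed_points must be strictly ascending", it$item_id)
    }
    if (pts[1] != 0) {
      stop_with("scale_validation_error",
                "item '%s': allowed_points must contain 0", it$item_id)
    }
    if (max(pts) <= 0) {
      stop_with("scale_validation_error",
                "item '%s': maximum allowed points must be positive", it$item_id)
    }
    list(item_id = it$item_id, label = it$label %||% it$item_id,
         part_id = part$part_id, allowed_points = pts,
         skippable = isTRUE(it$skippable %||% TRUE))
  })
  pmax_ <- sum(vapply(items, function(it) max(it$allowed_points), numeric(1)))
  if (!is.null(part$part_max) && abs(part$part_max - pmax_) > 1e-9) {
    stop_with("scale_integrity_error",
              "part %s: declared part_max %s != sum of item maxima %s",
              part$part_id, part$part_max, pmax_)
  }
  list(part_id = part$part_id, name = part$name, items = items,
       part_max = pmax_)
}

#' Tabulate the items of a scale definition
#'
#' @param scale a `scale_definition`.
#' @return a data.frame with one row per item: `item_id`, `label`,
#'   `part_id`, `max_points`, `skippable`, and a list-column
#'   `allowed_points`.
#' @export
scale_items <- function(scale) {
  stopifnot(inherits(scale, "scale_definition"))
  rows <- lapply(scale$parts, function(p) {
    data.frame(
      item_id = vapply(p$items, `[[`, character(1), "item_id"),
      label = vapply(p$items, `[[`, character(1), "label"),
      part_id = p$part_id,
      max_points = vapply(p$items, function(it) max(it$allowed_points),
                          numeric(1)),
      skippable = vapply(p$items, `[[`, logical(1), "skippable"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$allowed_points <- lapply(unlist(lapply(scale$parts, `[[`, "items"),
                                      recursive = FALSE), `[[`, "allowed_points")
  rownames(out) <- NULL
  out
}

#' Skip-adjusted maximum attainable score
#'
#' When parts of the examination cannot be performed (an uncooperative or
#' dangerous mare), the maximum attainable score is reduced by the maxima
#' of the skipped items, and pain is later expressed as a percentage of
#' this adjusted maximum.  Skipping the palpation blocks (parts 4 and 6)
#' of the bundled scale, for instance, reduces the maximum from 47 to 42.
#'
#' @param scale a `scale_definition`.
#' @param skipped character vector of skipped `item_id`s (default none).
#' @return the adjusted maximum, in points.
#' @export
#' @examples
#' sc <- bundled_scale()
#' it <- scale_items(sc)
#' scale_maximum(sc)                                        # 47
#' scale_maximum(sc, it$item_id[it$part_id %in% c(4, 6)])   # 42
scale_maximum <- function(scale, skipped = character()) {
  stopifnot(inherits(scale, "scale_definition"))
  items <- scale_items(scale)
  skipped <- unique(as.character(skipped))
  unknown <- setdiff(skipped, items$item_id)
  if (length(unknown)) {
    stop_with("scale_lookup_error", "unknown item id(s): %s",
              paste(unknown, collapse = ", "))
  }
  adj <- scale$total_max - sum(items$max_points[items$item_id %in% skipped])
  if (adj <= 0) {
    stop_with("degenerate_scale_error",
              "all scoring items skipped: adjusted maximum would be 0")
  }
  adj
}

#' Serialize a scale definition to JSON
#'
#' Writes the definition in the same document format accepted by
#' [load_scale()]; computed part and total maxima are included as
#' declarations so that hand edits to a written file are caught on reload.
#'
#' @param scale a `scale_definition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  doc <- list(
    scale_id = scale$scale_id, version = scale$version,
    parts = lapply(scale$parts, function(p) {
      list(part_id = p$part_id, name = p$name, part_max = p$part_max,
           items = lapply(p$items, function(it) {
             list(item_id = it$item_id, label = it$label,
                  allowed_points = it$allowed_points,
                  skippable = it$skippable)
           }))
    }),
    total_max = scale$total_max
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("<scale_definition> %s v%s\n", x$scale_id, x$version))
  for (p in x$parts) {
    cat(sprintf("  part %s: %s (%d items, max %g)\n",
                p$part_id, p$name, length(p$items), p$part_max))
  }
  cat(sprintf("  total maximum: %g points\n", x$total_max))
  invisible(x)
}
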