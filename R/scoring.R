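#' Construct a single scoring event
#'
#' One assessment of one mare at one time: a response for every item of the
#' instrument, each either scored with a permitted point value or skipped.
#' Responses may be given either as a data.frame (`item_id`, `status`,
#' `points`) or, more conveniently, as a named numeric vector of scored
#' points plus a character vector of skipped item ids; items present in
#' neither are treated as scored 0 when `fill_zero = TRUE` (the web form's
#' behaviour of defaulting untouched questions to "no sign observed"), and
#' rejected otherwise.
#'
#' @param mare_id identifier of the mare.
#' @param timestamp a `POSIXct` (or string parseable by [as.POSIXct()]).
#' @param points named numeric vector: scored points per `item_id`.
#' @param skipped character vector of skipped item ids.
#' @param scale a `scale_definition`; required with `fill_zero = TRUE`.
#' @param fill_zero fill unmentioned items with 0 points (default FALSE).
#' @param session optional "morning"/"evening" tag; inferred from the
#'   timestamp hour (< 14:00 is morning) when `NULL`.
#' @param notes free-text note.
#' @return an `assessment` object.
#' @export
assessment <- function(mare_id, timestamp, points = numeric(),
                       skipped = character(), scale = NULL,
                       fill_zero = FALSE, session = NULL, notes = "") {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (is.na(timestamp)) {
    stop_with("assessment_validation_error", "unparseable timestamp")
  }
  if (length(points) && is.null(names(points))) {
    stop_with("assessment_validation_error", "'points' must be named by item_id")
  }
  responses <- data.frame(
    item_id = c(names(points), as.character(skipped)),
    status = c(rep("scored", length(points)), rep("skipped", length(skipped))),
    points = c(unname(points), rep(NA_real_, length(skipped))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(responses$item_id)) {
    stop_with("assessment_validation_error",
              "duplicate response for item(s): %s",
              paste(unique(responses$item_id[duplicated(responses$item_id)]),
                    collapse = ", "))
  }
  if (fill_zero) {
    if (is.null(scale)) {
      stop_with("assessment_validation_error",
                "fill_zero = TRUE requires 'scale'")
    }
    missing_ids <- setdiff(scale_items(scale)$item_id, responses$item_id)
    if (length(missing_ids)) {
      responses <- rbind(responses, data.frame(
        item_id = missing_ids, status = "scored", points = 0,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(session)) {
    session <- if (as.integer(format(timestamp, "%H")) < 14) "morning" else "evening"
  }
  structure(
    list(mare_id = as.character(mare_id), timestamp = timestamp,
         session = session, responses = responses, notes = notes),
    class = "assessment"
  )
}

# check responses against the instrument; returns the responses data.frame
# augmented with part_id, erroring on unknown ids, duplicates, gaps and
# point values outside an item's allowed set
validate_responses <- function(a, scale) {
  items <- scale_items(scale)
  resp <- a$responses
  unknown <- setdiff(resp$item_id, items$item_id)
  if (length(unknown)) {
    stop_with("assessment_validation_error", "unknown item id(s): %s",
              paste(unknown, collapse = ", "))
  }
  missing_ids <- setdiff(items$item_id, resp$item_id)
  if (length(missing_ids)) {
    stop_with("assessment_validation_error",
              "no response for item(s): %s", paste(missing_ids, collapse = ", "))
  }
  if (anyDuplicated(resp$item_id)) {
    stop_with("assessment_validation_error", "duplicate item responses")
  }
  idx <- match(resp$item_id, items$item_id)
  resp$part_id <- items$part_id[idx]
  for (i in seq_len(nrow(resp))) {
    if (resp$status[i] == "scored") {
      allowed <- items$allowed_points[[idx[i]]]
      if (is.na(resp$points[i]) ||
          !any(abs(allowed - resp$points[i]) < 1e-9)) {
        stop_with("assessment_validation_error",
                  "item '%s': %s points not in allowed set {%s}",
                  resp$item_id[i], format(resp$points[i]),
                  paste(allowed, collapse = ", "))
      }
    } else if (resp$status[i] == "skipped") {
      if (!is.na(resp$points[i])) {
        stop_with("assessment_validation_error",
                  "item '%s': skipped response must not carry points",
                  resp$item_id[i])
      }
    } else {
      stop_with("assessment_validation_error",
                "item '%s': status must be 'scored' or 'skipped'",
                resp$item_id[i])
    }
  }
  resp
}

#' Score an assessment against a scale
#'
#' Sums the awarded points, computes the skip-adjusted maximum, expresses
#' the total as a percentage of that maximum (rounded half-up to one
#' decimal, the form's reporting precision), and classifies the mare
#' against the analgesia threshold.  A mare scoring 16 of an adjusted
#' maximum of 42 therefore reports 38.1\%.
#'
#' @param a an [assessment()].
#' @param scale a `scale_definition`.
#' @param threshold analgesia decision threshold in percent (default 40).
#' @param boundary_policy what to do at exactly the threshold: `"strict"`
#'   (the default; treatment only *above* the threshold) or `"treat"`
#'   (treatment at the threshold too).  See [classify()].
#' @return a `score_result`: `total_points`, `adjusted_max`, `percent`,
#'   `per_part` (data.frame of part totals), `classification`, plus the
#'   assessment's identifiers.
#' @export
#' @examples
#' sc <- bundled_scale()
#' it <- scale_items(sc)
#' palpation <- it$item_id[it$part_id %in% c(4, 6)]
#' a <- assessment("mare_07", "2025-03-02 08:00",
#'                 points = c(posture_weight = 3, body_position = 2,
#'                            abdomen_interest = 4, surroundings_response = 2,
#'                            head_wrinkles = 2, ear_position = 1,
#'                            eyelids = 1, respiratory_rate = 1),
#'                 skipped = palpation, scale = sc, fill_zero = TRUE)
#' r <- score_assessment(a, sc)
#' r$percent   # 38.1
score_assessment <- function(a, scale, threshold = 40,
                             boundary_policy = c("strict", "treat")) {
  stopifnot(inherits(a, "assessment"), inherits(scale, "scale_definition"))
  boundary_policy <- match.arg(boundary_policy)
  resp <- validate_responses(a, scale)
  skipped <- resp$item_id[resp$status == "skipped"]
  if (length(skipped) == nrow(resp)) {
    stop_with("degenerate_scale_error",
              "all items skipped: no score can be computed")
  }
  adjusted_max <- scale_maximum(scale, skipped)
  scored <- resp[resp$status == "scored", , drop = FALSE]
  total <- sum(scored$points)
  per_part <- stats::aggregate(points ~ part_id, data = scored, FUN = sum)
  names(per_part) <- c("part_id", "points")
  percent <- round_half_up(100 * total / adjusted_max, 1)
  structure(
    list(mare_id = a$mare_id, timestamp = a$timestamp, session = a$session,
         total_points = total, adjusted_max = adjusted_max,
         percent = percent, per_part = per_part,
         n_skipped = length(skipped),
         classification = classify(percent, threshold, boundary_policy)),
    class = "score_result"
  )
}

#' Classify a percentage pain score
#'
#' Scores above the threshold indicate that analgesic treatment is
#' warranted; scores below it indicate minimal to no discomfort.  A score
#' of exactly the threshold is not covered by that rule, so the boundary is
#' a policy choice: the default `"strict"` maps it to `"minimal-to-none"`,
#' `"treat"` maps it to `"analgesia-indicated"`.
#'
#' @param percent percentage score(s) in `[0, 100]`.
#' @param threshold decision threshold in percent (default 40).
#' @param boundary_policy `"strict"` or `"treat"`, see above.
#' @return character vector: `"analgesia-indicated"` or `"minimal-to-none"`.
#' @export
#' @examples
#' classify(c(28, 40, 47))          # minimal, minimal, analgesia
#' classify(40, boundary_policy = "treat")
classify <- function(percent, threshold = 40,
                     boundary_policy = c("strict", "treat")) {
  boundary_policy <- match.arg(boundary_policy)
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    stop_with("score_validation_error",
              "percent must lie in [0, 100]")
  }
  hit <- if (boundary_policy == "strict") percent > threshold else percent >= threshold
  ifelse(hit, "analgesia-indicated", "minimal-to-none")
}

#' Serial scoring trajectory for one mare
#'
#' Serial scoring is more informative than a single assessment: persistent
#' or rising scores can flag complications (the study's colon-torsion mare
#' went 12\%, 15\%, 47\% over three sessions).  This orders a mare's
#' assessments in time, scores each, computes the change between
#' consecutive percentages, and raises an escalation flag when the
#' percentage rises over consecutive assessments or any score exceeds the
#' treatment threshold.
#'
#' @param assessments list of [assessment()] objects for one mare.
#' @param scale a `scale_definition`.
#' @param threshold analgesia threshold in percent (default 40).
#' @param boundary_policy see [classify()].
#' @return a `pain_trajectory`: `mare_id`, a data.frame `scores`
#'   (timestamp, session, total, adjusted_max, percent, classification,
#'   delta), and `escalation_flag`.
#' @export
build_trajectory <- function(assessments, scale, threshold = 40,
                             boundary_policy = c("strict", "treat")) {
  boundary_policy <- match.arg(boundary_policy)
  stopifnot(length(assessments) >= 1L,
            all(vapply(assessments, inherits, logical(1), "assessment")))
  ids <- unique(vapply(assessments, `[[`, character(1), "mare_id"))
  if (length(ids) != 1L) {
    stop_with("trajectory_validation_error",
              "assessments span several mares: %s", paste(ids, collapse = ", "))
  }
  times <- as.POSIXct(vapply(assessments, function(a) {
    as.numeric(a$timestamp)
  }, numeric(1)), origin = "1970-01-01", tz = "UTC")
  if (anyDuplicated(times)) {
    stop_with("trajectory_validation_error", "duplicate assessment timestamps")
  }
  ord <- order(times)
  results <- lapply(assessments[ord], score_assessment, scale = scale,
                    threshold = threshold, boundary_policy = boundary_policy)
  percent <- vapply(results, `[[`, numeric(1), "percent")
  scores <- data.frame(
    timestamp = times[ord],
    session = vapply(results, `[[`, character(1), "session"),
    total_points = vapply(results, `[[`, numeric(1), "total_points"),
    adjusted_max = vapply(results, `[[`, numeric(1), "adjusted_max"),
    percent = percent,
    classification = vapply(results, `[[`, character(1), "classification"),
    delta = c(NA_real_, diff(percent)),
    stringsAsFactors = FALSE
  )
  rising <- length(percent) >= 2L && any(diff(percent) > 0)
  over <- if (boundary_policy == "strict") any(percent > threshold) else any(percent >= threshold)
  structure(
    list(mare_id = ids, scores = scores,
         escalation_flag = rising || over),
    class = "pain_trajectory"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> mare %s @ %s (%s)\n", x$mare_id,
              format(x$timestamp, "%Y-%m-%d %H:%M"), x$session))
  cat(sprintf("  total %g / %g points (%d item(s) skipped)\n",
              x$total_points, x$adjusted_max, x$n_skipped))
  cat(sprintf("  pain score: %.1f%% -> %s\n", x$percent, x$classification))
  invisible(x)
}

#' @export
print.pain_trajectory <- function(x, ...) {
  cat(sprintf("<pain_trajectory> mare %s, %d assessment(s), escalation: %s\n",
              x$mare_id, nrow(x$scores), x$escalation_flag))
  print(x$scores, row.names = FALSE)
  invisible(x)
}
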