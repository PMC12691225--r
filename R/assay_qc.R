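#' Quality-control configuration for cortisol replicates
#'
#' @param floor absolute lower plausibility bound in pg/mL (default 22):
#'   salivary cortisol readings below it are treated as pipetting errors
#'   and removed.  The filter is strict: exactly 22.0 is retained.
#' @param projection_alpha per-side tail probability of the projection
#'   screen's chi-square cutoff (default 0.025, i.e. the 0.95 two-sided /
#'   chi-square 0.975 quantile).
#' @param min_replicates minimum retained technical replicates per mare
#'   and sampling time for the sample to enter the model (default 2).
#' @return a `qc_config` list.
#' @export
qc_config <- function(floor = 22, projection_alpha = 0.025,
                      min_replicates = 2) {
  stopifnot(floor > 0, projection_alpha > 0, projection_alpha < 0.5,
            min_replicates >= 1)
  structure(list(floor = floor, projection_alpha = projection_alpha,
                 min_replicates = min_replicates), class = "qc_config")
}

#' Flag implausibly low cortisol values
#'
#' Marks replicate measurements strictly below the floor (default
#' 22 pg/mL) as `floor_removed`; everything else keeps its current flag.
#'
#' @param panel data.frame with at least a `cortisol_pg_ml` column;
#'   a `qc_flag` column is added/updated.
#' @param cfg a [qc_config()].
#' @return `panel` with `qc_flag` set to `"floor_removed"` or
#'   `"retained"`.
#' @export
floor_filter <- function(panel, cfg = qc_config()) {
  stopifnot(is.data.frame(panel), "cortisol_pg_ml" %in% names(panel))
  y <- panel$cortisol_pg_ml
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_with("qc_validation_error",
              "cortisol values must be positive and finite")
  }
  if (is.null(panel$qc_flag)) panel$qc_flag <- "retained"
  panel$qc_flag[panel$qc_flag == "retained" & y < cfg$floor] <- "floor_removed"
  panel
}

#' Robust multivariate outlier screen by projection
#'
#' Projection-depth screening in the spirit of the outlier-projection
#' method of robust statistics: the data are centred at the
#' coordinate-wise median; for every observation the direction from the
#' centre through that observation is taken, all points are projected onto
#' it, and each projection is standardised by its median and normalised
#' MAD (MAD / 0.6745).  A point is declared an outlier if, in *any* of
#' these data-driven projections, its absolute robust z-score exceeds
#' `sqrt(qchisq(1 - alpha, p))` -- the chi-square 0.975 quantile at the
#' default `alpha`, the documented cutoff of this method family.  The
#' screen is deterministic given the data.
#'
#' @param points numeric matrix (n observations x p coordinates), n >= 3.
#' @param alpha per-side tail probability (default 0.025, giving the
#'   chi-square 0.975 cutoff).
#' @return logical vector of length n: `TRUE` for flagged points.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(rnorm(20), rnorm(20))
#' x <- rbind(x, c(10, 10))
#' which(projection_outliers(x))   # 21
projection_outliers <- function(points, alpha = 0.025) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points); p <- ncol(points)
  if (n < 3L) {
    stop_with("qc_insufficient_data_error",
              "projection screen needs at least 3 points, got %d", n)
  }
  if (any(!is.finite(points))) {
    stop_with("qc_validation_error", "non-finite values in projection input")
  }
  stopifnot(alpha > 0, alpha < 0.5)
  center <- apply(points, 2, stats::median)
  cutoff <- sqrt(stats::qchisq(1 - alpha, df = p))
  flagged <- rep(FALSE, n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    d <- points[i, ] - center
    len <- sqrt(sum(d^2))
    if (len < .Machine$double.eps^0.5) next  # point at the centre: no direction
    proj <- as.numeric(points %*% (d / len))
    med <- stats::median(proj)
    madn <- stats::mad(proj, center = med)  # already scaled by 1/0.6745
    if (madn < .Machine$double.eps^0.5) {
      degenerate <- degenerate + 1L
      next
    }
    flagged <- flagged | (abs(proj - med) / madn > cutoff)
  }
  if (degenerate > 0L) {
    warn_with("qc_degenerate_projection_warning",
              "%d projection(s) had zero MAD and were skipped", degenerate)
  }
  flagged
}

#' Enforce a minimum replicate count per sample
#'
#' After outlier removal every sampling time must keep at least
#' `min_replicates` technical replicates for its mare; samples below the
#' minimum are listed as failures and should be excluded from modelling.
#'
#' @param panel data.frame with `mare_id`, `timestamp`, `qc_flag`.
#' @param cfg a [qc_config()].
#' @return a `qc_report`: removal counts by reason, per-sample retained
#'   replicate counts, and the failing samples.
#' @export
enforce_replicates <- function(panel, cfg = qc_config()) {
  stopifnot(is.data.frame(panel),
            all(c("mare_id", "timestamp", "qc_flag") %in% names(panel)))
  retained <- panel[panel$qc_flag == "retained", , drop = FALSE]
  key_all <- unique(panel[, c("mare_id", "timestamp")])
  if (nrow(retained)) {
    counts <- stats::aggregate(
      list(n_retained = retained$qc_flag),
      by = list(mare_id = retained$mare_id,
                timestamp = retained$timestamp),
      FUN = length)
    counts <- merge(key_all, counts, all.x = TRUE)
    counts$n_retained[is.na(counts$n_retained)] <- 0L
  } else {
    counts <- key_all
    counts$n_retained <- 0L
  }
  counts <- counts[order(counts$mare_id, counts$timestamp), , drop = FALSE]
  rownames(counts) <- NULL
  failures <- counts[counts$n_retained < cfg$min_replicates, , drop = FALSE]
  structure(
    list(n_floor_removed = sum(panel$qc_flag == "floor_removed"),
         n_projection_removed = sum(panel$qc_flag == "projection_removed"),
         n_retained = sum(panel$qc_flag == "retained"),
         sample_counts = counts, failures = failures,
         config = cfg),
    class = "qc_report"
  )
}

#' Full replicate quality-control pipeline
#'
#' Single-pass screening as used before the cortisol validation model:
#' (1) remove replicates below the absolute floor; (2) run the projection
#' outlier screen once on the feature vectors of the remaining replicates
#' (by default the (pain percent, cortisol) pair, the plane in which the
#' model operates); (3) check that every sample keeps the minimum number
#' of technical replicates.
#'
#' @param panel data.frame with `mare_id`, `timestamp`,
#'   `replicate_index`, `cortisol_pg_ml` and the feature columns.
#' @param cfg a [qc_config()].
#' @param features columns forming the outlier-screen feature space
#'   (default `c("pain_percent", "cortisol_pg_ml")`).  Columns absent from
#'   the panel are dropped with a warning, so a panel without pain scores
#'   falls back to a univariate cortisol screen.
#' @return list with `panel` (flags filled in) and `report`
#'   (a `qc_report`).
#' @export
run_qc <- function(panel, cfg = qc_config(),
                   features = c("pain_percent", "cortisol_pg_ml")) {
  panel <- floor_filter(panel, cfg)
  present <- intersect(features, names(panel))
  if (length(present) < length(features)) {
    warn_with("qc_missing_feature_warning",
              "feature column(s) %s not in panel; screening on %s",
              paste(setdiff(features, present), collapse = ", "),
              paste(present, collapse = ", "))
  }
  if (length(present) == 0L) {
    stop_with("qc_validation_error", "no feature columns available for screening")
  }
  keep <- panel$qc_flag == "retained"
  if (sum(keep) >= 3L) {
    X <- as.matrix(panel[keep, present, drop = FALSE])
    out <- projection_outliers(X, alpha = cfg$projection_alpha)
    panel$qc_flag[keep][out] <- "projection_removed"
  } else {
    warn_with("qc_insufficient_data_warning",
              "fewer than 3 retained replicates; projection screen skipped")
  }
  list(panel = panel, report = enforce_replicates(panel, cfg))
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  floor-removed:      %d (cortisol < %g pg/mL)\n",
              x$n_floor_removed, x$config$floor))
  cat(sprintf("  projection-removed: %d\n", x$n_projection_removed))
  cat(sprintf("  retained:           %d replicates over %d samples\n",
              x$n_retained, nrow(x$sample_counts)))
  if (nrow(x$failures)) {
    cat(sprintf("  FAILURES (< %d replicates):\n", x$config$min_replicates))
    print(x$failures, row.names = FALSE)
  } else {
    cat(sprintf("  all samples keep >= %d replicates\n", x$config$min_replicates))
  }
  invisible(x)
}
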