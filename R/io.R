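#' Read a cortisol replicate CSV
#'
#' Expected columns: `mare_id`, `timestamp` (ISO-8601), `replicate_index`,
#' `cortisol_pg_ml` (decimal point, UTF-8, comma-separated).  Column names
#' in the file can be remapped through `mapping`.  Malformed rows are
#' reported with their file line numbers; in strict mode (default) any
#' malformed row aborts the read, otherwise bad rows are dropped with a
#' warning.
#'
#' @param path CSV file path.
#' @param mapping optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(mare_id = "horse")`.
#' @param strict abort on malformed rows (default TRUE).
#' @return data.frame with the canonical columns, timestamps as POSIXct.
#' @export
read_cortisol <- function(path, mapping = NULL, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- apply_mapping(df, mapping)
  need <- c("mare_id", "timestamp", "replicate_index", "cortisol_pg_ml")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_with("io_schema_error", "%s: missing column(s) %s", path,
              paste(miss, collapse = ", "))
  }
  ts <- parse_timestamp(df$timestamp)
  y <- suppressWarnings(as.numeric(df$cortisol_pg_ml))
  k <- suppressWarnings(as.integer(df$replicate_index))
  bad <- which(is.na(ts) | is.na(y) | y <= 0 | is.na(k))
  if (length(bad)) {
    msg <- sprintf("%s: malformed row(s) at line(s) %s", path,
                   paste(bad + 1L, collapse = ", "))  # +1 for header
    if (strict) stop_with("io_row_error", "%s", msg)
    warn_with("io_row_warning", "%s (dropped)", msg)
    keep <- setdiff(seq_len(nrow(df)), bad)
    df <- df[keep, , drop = FALSE]; ts <- ts[keep]; y <- y[keep]; k <- k[keep]
  }
  out <- data.frame(mare_id = as.character(df$mare_id), timestamp = ts,
                    replicate_index = k, cortisol_pg_ml = y,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(need, "timestamp"))
  for (col in extra) out[[col]] <- df[[col]]
  out
}

# parse timestamps against the accepted formats, NA (not an error) on
# failure so malformed rows can be reported by line number
parse_timestamp <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

apply_mapping <- function(df, mapping) {
  if (is.null(mapping)) return(df)
  for (canonical in names(mapping)) {
    if (mapping[[canonical]] %in% names(df)) {
      names(df)[names(df) == mapping[[canonical]]] <- canonical
    }
  }
  df
}

#' Read item-level assessment forms from a long CSV
#'
#' One row per item response: `mare_id`, `timestamp`, `item_id`, `status`
#' (`scored`/`skipped`), `points` (empty for skipped rows).  Rows are
#' grouped by mare and timestamp into [assessment()] objects.
#'
#' @param path CSV file path.
#' @param mapping optional column-name mapping, see [read_cortisol()].
#' @param strict abort on malformed rows (default TRUE).
#' @return list of `assessment` objects.
#' @export
read_assessments <- function(path, mapping = NULL, strict = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- apply_mapping(df, mapping)
  need <- c("mare_id", "timestamp", "item_id", "status", "points")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_with("io_schema_error", "%s: missing column(s) %s", path,
              paste(miss, collapse = ", "))
  }
  ts <- parse_timestamp(df$timestamp)
  pts <- suppressWarnings(as.numeric(df$points))
  bad <- which(is.na(ts) | !df$status %in% c("scored", "skipped") |
                 (df$status == "scored" & is.na(pts)))
  if (length(bad)) {
    msg <- sprintf("%s: malformed row(s) at line(s) %s", path,
                   paste(bad + 1L, collapse = ", "))
    if (strict) stop_with("io_row_error", "%s", msg)
    warn_with("io_row_warning", "%s (dropped)", msg)
    keep <- setdiff(seq_len(nrow(df)), bad)
    df <- df[keep, , drop = FALSE]; ts <- ts[keep]; pts <- pts[keep]
  }
  key <- paste(df$mare_id, format(ts, "%Y-%m-%dT%H:%M:%S"), sep = "|")
  lapply(split(seq_len(nrow(df)), key), function(rows) {
    scored <- rows[df$status[rows] == "scored"]
    skipped <- rows[df$status[rows] == "skipped"]
    assessment(mare_id = df$mare_id[rows[1]], timestamp = ts[rows[1]],
               points = stats::setNames(pts[scored], df$item_id[scored]),
               skipped = df$item_id[skipped])
  })
}

#' Write assessments to a long CSV
#'
#' @param assessments list of [assessment()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  rows <- lapply(assessments, function(a) {
    data.frame(mare_id = a$mare_id,
               timestamp = format(a$timestamp, "%Y-%m-%dT%H:%M:%S"),
               item_id = a$responses$item_id, status = a$responses$status,
               points = a$responses$points, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cortisol panel to CSV
#'
#' @param panel replicate-level data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cortisol <- function(panel, path) {
  out <- panel
  if (inherits(out$timestamp, "POSIXct")) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write any report object as JSON
#'
#' Strips classes and serializes with unboxed scalars and full numeric
#' precision, so reports round-trip losslessly.
#'
#' @param x report object (score result, QC report, posterior summary...).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(strip_classes(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, POSIXt = "ISO8601",
                       na = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, function(col) {
    if (inherits(col, "POSIXct")) format(col, "%Y-%m-%dT%H:%M:%S") else col
  }), stringsAsFactors = FALSE))
  if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%dT%H:%M:%S"))
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

#' Score a batch of assessments
#'
#' @param assessments list of [assessment()] objects (possibly several
#'   mares).
#' @param scale a `scale_definition`.
#' @param ... passed to [score_assessment()] (threshold, boundary policy).
#' @return long-format data.frame: one row per assessment with
#'   `mare_id`, `timestamp`, `session`, `total_points`, `adjusted_max`,
#'   `percent`, `classification`.
#' @export
score_batch <- function(assessments, scale, ...) {
  rows <- lapply(assessments, function(a) {
    r <- score_assessment(a, scale, ...)
    data.frame(mare_id = r$mare_id, timestamp = r$timestamp,
               session = r$session, total_points = r$total_points,
               adjusted_max = r$adjusted_max, percent = r$percent,
               classification = r$classification, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mare_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach pain scores to a cortisol panel
#'
#' Joins percentage pain scores onto replicate measurements by mare and
#' sampling time, producing the feature table the QC screen and the
#' validation model operate on.
#'
#' @param panel replicate-level cortisol data.frame (`mare_id`,
#'   `timestamp`, ...).
#' @param scores data.frame from [score_batch()] (or any with `mare_id`,
#'   `timestamp`, `percent`).
#' @return `panel` with a `pain_percent` column; replicates without a
#'   matching assessment get `NA`.
#' @export
join_pain <- function(panel, scores) {
  stopifnot(all(c("mare_id", "timestamp") %in% names(panel)),
            all(c("mare_id", "timestamp", "percent") %in% names(scores)))
  key_p <- paste(panel$mare_id, format(panel$timestamp, "%Y-%m-%dT%H:%M"))
  key_s <- paste(scores$mare_id, format(scores$timestamp, "%Y-%m-%dT%H:%M"))
  panel$pain_percent <- scores$percent[match(key_p, key_s)]
  panel
}

#' Run the full cortisol validation pipeline
#'
#' One-shot reproduction path: score the assessments, join pain scores to
#' the replicate panel, run replicate QC (floor filter, projection screen,
#' replicate-count enforcement), fit the Bayesian mixed model, summarise,
#' run convergence diagnostics and both sensitivity analyses, and
#' optionally write every report to an output directory.
#'
#' @param config a list (or path to a JSON file encoding one) with
#'   entries: `cortisol` (path or data.frame), `assessments` (path or
#'   list; optional if the panel already has `pain_percent`), `scale`
#'   (path or `scale_definition`; default the bundled instrument), `qc`
#'   (arguments for [qc_config()]), `priors` (arguments for
#'   [prior_spec()]), `mcmc` (arguments for [mcmc_spec()]),
#'   `leverage_pain` (default 28), `seed`, `out_dir` (optional).
#' @return a `validation_report`: `qc_report`, `summary`, `diagnostics`,
#'   `leverage`, `default_prior`, `fit`, `n_model_obs`, `config_hash`,
#'   `package_version`.  Written files: `qc_report.json`,
#'   `posterior_summary.json`, `diagnostics.json`,
#'   `sensitivity_leverage.json`, `sensitivity_default_prior.json`,
#'   `summary.txt`.
#' @export
run_validation <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  # hash the analysis-relevant configuration only, not output locations
  config_hash <- hash_config(config[setdiff(names(config), "out_dir")])
  scale <- config$scale %||% bundled_scale()
  if (is.character(scale)) scale <- load_scale(scale)
  panel <- config$cortisol
  if (is.character(panel)) panel <- read_cortisol(panel)
  if (is.null(panel)) stop_with("config_error", "config lacks 'cortisol'")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  message(sprintf("[validate] %d replicate rows loaded", nrow(panel)))
  if (!"pain_percent" %in% names(panel)) {
    a <- config$assessments
    if (is.character(a)) a <- read_assessments(a)
    if (is.null(a)) {
      stop_with("config_error",
                "panel has no pain_percent and config lacks 'assessments'")
    }
    scores <- score_batch(a, scale)
    panel <- join_pain(panel, scores)
    message(sprintf("[validate] scored %d assessments", nrow(scores)))
  }
  if (anyNA(panel$pain_percent)) {
    stop_with("pipeline_error",
              "%d replicate row(s) have no matching pain score",
              sum(is.na(panel$pain_percent)))
  }

  cfg <- do.call(qc_config, as.list(config$qc %||% list()))
  qc <- run_qc(panel, cfg)
  message(sprintf("[validate] QC: %d floor-removed, %d projection-removed, %d retained",
                  qc$report$n_floor_removed, qc$report$n_projection_removed,
                  qc$report$n_retained))
  clean <- qc$panel[qc$panel$qc_flag == "retained", , drop = FALSE]
  if (nrow(qc$report$failures)) {
    bad_key <- paste(qc$report$failures$mare_id, qc$report$failures$timestamp)
    drop <- paste(clean$mare_id, clean$timestamp) %in% bad_key
    warn_with("pipeline_warning",
              "%d sample(s) below the replicate minimum excluded from the model",
              nrow(qc$report$failures))
    clean <- clean[!drop, , drop = FALSE]
  }
  if (nrow(clean) == 0L) {
    stop_with("pipeline_error", "no replicates retained after QC")
  }

  md <- model_data(clean)
  priors <- do.call(prior_spec, as.list(config$priors %||% list()))
  mcmc_args <- as.list(config$mcmc %||% list())
  if (is.null(mcmc_args$seed) && !is.null(config$seed)) {
    mcmc_args$seed <- as.integer(config$seed)
  }
  mcmc <- do.call(mcmc_spec, mcmc_args)
  message(sprintf("[validate] fitting on %d observations from %d mares (seed %d)",
                  nrow(md), attr(md, "n_mares"), mcmc$seed))
  fit <- fit_model(md, priors, mcmc)
  summ <- summarize_posterior(fit)
  diag_ <- fit_diagnostics(fit)
  if (!diag_$pass) {
    warn_with("pipeline_warning", "MCMC diagnostics failed: report marked not converged")
  }
  lev <- sensitivity_leverage(md, priors, mcmc,
                              leverage_pain = config$leverage_pain %||% 28,
                              full_fit = fit)
  dp <- sensitivity_default_prior(md, mcmc, base_priors = priors)
  message(sprintf("[validate] slope %.2f (CrI %.2f..%.2f); leverage-removed %.2f; default-prior %.2f",
                  summ$slope_median, summ$cri$lower, summ$cri$upper,
                  lev$reduced$slope_median, dp$summary$slope_median))

  report <- structure(
    list(qc_report = qc$report, summary = summ, diagnostics = diag_,
         leverage = lev, default_prior = dp, fit = fit,
         n_model_obs = nrow(md), converged = diag_$pass,
         config_hash = config_hash,
         package_version = as.character(utils::packageVersion("marepain"))),
    class = "validation_report"
  )
  if (!is.null(config$out_dir)) write_validation_report(report, config$out_dir)
  report
}

hash_config <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_validation_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(config_hash = report$config_hash,
                     package_version = report$package_version)
  wr <- function(x, file) {
    write_report(c(strip_classes(x), provenance), file.path(out_dir, file))
  }
  wr(report$qc_report, "qc_report.json")
  wr(report$summary, "posterior_summary.json")
  wr(report$diagnostics, "diagnostics.json")
  wr(list(full = report$leverage$full, reduced = report$leverage$reduced,
          n_removed = report$leverage$n_removed), "sensitivity_leverage.json")
  wr(list(summary = report$default_prior$summary,
          slope_prior_sd = report$default_prior$slope_prior_sd),
     "sensitivity_default_prior.json")
  txt <- utils::capture.output({
    print(report$qc_report); print(report$summary); print(report$diagnostics)
    print(report$leverage); print(report$default_prior)
  })
  writeLines(c(sprintf("marepain %s  (config %s)", report$package_version,
                       report$config_hash), txt),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> marepain %s, config %s\n",
              x$package_version, x$config_hash))
  print(x$qc_report); print(x$summary); print(x$diagnostics)
  print(x$leverage); print(x$default_prior)
  invisible(x)
}
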