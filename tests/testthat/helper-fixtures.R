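# shared fixtures and independent oracles, all built in code

# a reduced two-part toy instrument, written through the JSON loader so the
# full load path is exercised
toy_scale <- function() {
  doc <- list(
    scale_id = "toy", version = "0.1",
    parts = list(
      list(part_id = 1, name = "behaviour", items = list(
        list(item_id = "A", label = "A", allowed_points = c(0, 1, 2)),
        list(item_id = "B", label = "B", allowed_points = c(0, 1)))),
      list(part_id = 2, name = "body", items = list(
        list(item_id = "C", label = "C", allowed_points = c(0, 0.5)),
        list(item_id = "D", label = "D", allowed_points = c(0, 2))))
    ))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  load_scale(path)
}

# study-condition generator settings: 5 mares with stays of 1-2 days
# (~14 sampling times), triplicates, assay CV 8.7%
paper_sized_params <- function(seed, ...) {
  generative_params(seed = seed, days = c(1, 1, 2, 2, 1), ...)
}

# brute-force projection-outlier oracle: explicit loops over every
# point-through-centre direction, scalar arithmetic only (independent of
# the package's vectorised implementation)
oracle_projection_flags <- function(X, alpha = 0.025) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  center <- numeric(p)
  for (k in seq_len(p)) center[k] <- median(X[, k])
  cutoff <- sqrt(qchisq(1 - alpha, df = p))
  flags <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d <- X[i, ] - center
    norm_d <- sqrt(sum(d * d))
    if (norm_d == 0) next
    proj <- numeric(n)
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(p)) s <- s + X[j, k] * d[k] / norm_d
      proj[j] <- s
    }
    m <- median(proj)
    madn <- median(abs(proj - m)) / 0.6745
    if (madn <= 1e-12) next
    for (j in seq_len(n)) {
      if (abs(proj[j] - m) / madn > cutoff) flags[j] <- TRUE
    }
  }
  flags
}

# an assessment scoring `total` points against the bundled scale with
# parts 4 and 6 skipped (adjusted maximum 42); total 16 by default
sixteen_of_42 <- function(scale) {
  it <- scale_items(scale)
  skip <- it$item_id[it$part_id %in% c(4, 6)]
  assessment("mare_x", "2026-01-02 08:00",
             points = c(posture_weight = 4, body_position = 4,
                        abdomen_interest = 4, head_wrinkles = 2,
                        ear_position = 1, respiratory_rate = 1),
             skipped = skip, scale = scale, fill_zero = TRUE)
}

# draw a random legal assessment on a scale; returns the assessment plus
# the raw sampled points for independent re-summation
random_assessment <- function(scale, mare = "m", time = "2026-01-01 08:00",
                              skip_prob = 0.15) {
  it <- scale_items(scale)
  skipped <- it$item_id[runif(nrow(it)) < skip_prob]
  if (length(skipped) == nrow(it)) skipped <- skipped[-1]
  scored <- setdiff(it$item_id, skipped)
  pts <- vapply(scored, function(id) {
    allowed <- it$allowed_points[[match(id, it$item_id)]]
    sample(allowed, 1)
  }, numeric(1))
  list(assessment = assessment(mare, time, points = pts, skipped = skipped),
       points = pts, skipped = skipped)
}

quick_mcmc <- function(seed = 1, iterations = 1500) {
  mcmc_spec(chains = 4, iterations = iterations, seed = seed)
}

# simulate a clean paper-sized cohort and return its model_data
quick_model_data <- function(seed, ...) {
  co <- simulate_panel(paper_sized_params(seed, ...))
  model_data(co$panel[, c("mare_id", "timestamp", "pain_percent",
                          "cortisol_pg_ml")])
}
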