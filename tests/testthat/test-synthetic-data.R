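test_that("parameter validation rejects impossible settings", {
  expect_error(generative_params(rho = 1), class = "params_validation_error")
  expect_error(generative_params(tau_a = -1), class = "params_validation_error")
  expect_error(generative_params(spike_rate = 2), class = "params_validation_error")
  expect_error(generative_params(n_mares = 0), class = "params_validation_error")
})

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_panel(paper_sized_params(123))
  b <- simulate_panel(paper_sized_params(123))
  expect_identical(a, b)
  c_ <- simulate_panel(paper_sized_params(124))
  expect_false(identical(a$panel$cortisol_pg_ml, c_$panel$cortisol_pg_ml))
})

test_that("replicate noise realises the configured intra-assay CV", {
  p <- generative_params(n_mares = 60, days = 2, seed = 9)
  co <- simulate_panel(p)
  cv <- with(co$panel, tapply(cortisol_pg_ml,
                              paste(mare_id, timestamp),
                              function(y) sd(y) / mean(y)))
  # triplicate sample CV is biased low (n = 3); correct with c4 ~ 0.8862
  expect_equal(mean(cv) / 0.8862, 0.087, tolerance = 0.08)
})

test_that("large clean cohorts recover the generating slope by OLS", {
  p <- generative_params(n_mares = 200, days = 4, tau_a = 20, tau_b = 1,
                         seed = 31)
  co <- simulate_panel(p)
  fit <- lm(cortisol_pg_ml ~ pain_percent, data = co$panel)
  expect_equal(unname(coef(fit)[2]), 13, tolerance = 0.15)
})

test_that("a null slope yields near-zero pooled correlation", {
  p <- generative_params(n_mares = 150, days = 3, beta0 = 0, tau_b = 0,
                         seed = 77)
  co <- simulate_panel(p)
  expect_lt(abs(cor(co$panel$pain_percent, co$panel$cortisol_pg_ml)), 0.06)
})

test_that("outlier injection labels points, keeps the clean panel, and bounds floors", {
  p <- paper_sized_params(55, n_floor_outliers = 2, n_displaced_outliers = 2)
  co <- inject_outliers(simulate_panel(p))
  expect_equal(sum(co$panel$outlier_type == "floor"), 2L)
  expect_equal(sum(co$panel$outlier_type == "displaced"), 2L)
  expect_true(all(co$panel$cortisol_pg_ml[co$panel$outlier_type == "floor"] < 22))
  expect_true(all(co$clean_panel$outlier_type == "none"))
  # contamination touches only labelled rows
  same <- co$panel$outlier_type == "none"
  expect_equal(co$panel$cortisol_pg_ml[same], co$clean_panel$cortisol_pg_ml[same])

  none <- inject_outliers(simulate_panel(paper_sized_params(56)))
  expect_identical(none$panel, none$clean_panel)

  too_many <- paper_sized_params(57, n_floor_outliers = 500)
  expect_error(inject_outliers(simulate_panel(too_many)),
               class = "contamination_error")
})

test_that("simulated assessments hit their target percentages through the scorer", {
  sc <- bundled_scale()
  set.seed(8)
  targets <- data.frame(
    mare_id = "m", timestamp = as.POSIXct("2026-01-01 08:00", tz = "UTC") +
      3600 * seq_len(300),
    pain_percent = round(runif(300, 0, 100), 1), stringsAsFactors = FALSE)
  p <- generative_params(seed = 14)
  sim <- simulate_assessments(p, sc, targets = targets)
  got <- vapply(sim$assessments, function(a) score_assessment(a, sc)$percent,
                numeric(1))
  expect_true(all(abs(got - targets$pain_percent) <= 3))
  expect_lt(mean(abs(got - targets$pain_percent)), 1)
})

test_that("assessment simulation honours skips and the boundary targets", {
  sc <- bundled_scale()
  t0 <- data.frame(mare_id = "m",
                   timestamp = as.POSIXct("2026-01-01 08:00", tz = "UTC"),
                   pain_percent = 0, stringsAsFactors = FALSE)
  a0 <- simulate_assessments(generative_params(seed = 2), sc, targets = t0)
  r0 <- score_assessment(a0$assessments[[1]], sc)
  expect_equal(r0$percent, 0)

  t100 <- t0; t100$pain_percent <- 100
  a100 <- simulate_assessments(generative_params(seed = 2), sc, targets = t100)
  r100 <- score_assessment(a100$assessments[[1]], sc)
  expect_equal(r100$percent, 100)
  expect_equal(r100$total_points, 47)

  pskip <- generative_params(seed = 3, skip_rate = 0.2)
  t5 <- t0[rep(1, 40), ]; t5$timestamp <- t5$timestamp + 3600 * seq_len(40)
  t5$pain_percent <- round(runif(40, 5, 45), 1)
  sim <- simulate_assessments(pskip, sc, targets = t5)
  n_skip <- vapply(sim$assessments,
                   function(a) sum(a$responses$status == "skipped"), numeric(1))
  expect_gt(sum(n_skip), 0)
  got <- vapply(sim$assessments, function(a) score_assessment(a, sc)$percent,
                numeric(1))
  expect_true(all(abs(got - t5$pain_percent) <= 3))

  bad <- t0; bad$pain_percent <- 120
  expect_error(simulate_assessments(generative_params(seed = 2), sc,
                                    targets = bad),
               class = "target_validation_error")
})

test_that("trajectory defaults produce paper-like percent ranges", {
  set.seed(19)
  panels <- do.call(rbind, lapply(1:20, function(s) {
    simulate_panel(paper_sized_params(600 + s))$panel
  }))
  expect_gt(mean(panels$pain_percent >= 3 & panels$pain_percent <= 47), 0.9)
  day1 <- panels$pain_percent[panels$day == 1]
  expect_gt(mean(day1), 8); expect_lt(mean(day1), 18)
})
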