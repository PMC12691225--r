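test_that("model data validation enforces the modelling invariants", {
  df <- data.frame(mare_id = c("a", "a", "b", "b"),
                   pain_percent = c(10, 20, 5, 15),
                   cortisol_pg_ml = c(200, 300, 150, 250))
  md <- model_data(df)
  expect_equal(attr(md, "n_mares"), 2L)
  expect_error(model_data(df[1:3, ]), class = "model_data_error")  # mare b once
  bad <- df; bad$cortisol_pg_ml[1] <- -5
  expect_error(model_data(bad), class = "model_data_error")
  bad2 <- df; bad2$pain_percent[1] <- 150
  expect_error(model_data(bad2), class = "model_data_error")
})

test_that("replicate means aggregation collapses technical replicates", {
  co <- simulate_panel(paper_sized_params(62))
  md_rep <- model_data(co$panel[, c("mare_id", "timestamp", "pain_percent",
                                    "cortisol_pg_ml")])
  md_mean <- model_data(co$panel[, c("mare_id", "timestamp", "pain_percent",
                                     "cortisol_pg_ml")], aggregate = "mean")
  expect_equal(nrow(md_rep), 3 * nrow(md_mean))
  key <- paste(md_rep$mare_id, md_rep$timestamp)
  means <- tapply(md_rep$cortisol_pg_ml, key, mean)
  expect_equal(sort(as.numeric(means)), sort(md_mean$cortisol_pg_ml))
})

test_that("slope prior SD scales as multiplier * SD(y)/SD(x)", {
  md <- quick_model_data(63)
  expect_equal(compute_slope_prior_sd(md),
               2 * sd(md$cortisol_pg_ml) / sd(md$pain_percent))
  expect_equal(compute_slope_prior_sd(md, multiplier = 0), 0)
  doubled <- as.data.frame(md)
  doubled$cortisol_pg_ml <- 2 * doubled$cortisol_pg_ml
  expect_equal(compute_slope_prior_sd(model_data(doubled)),
               2 * compute_slope_prior_sd(md))
  flat <- as.data.frame(md); flat$pain_percent <- 10
  expect_error(compute_slope_prior_sd(flat), class = "prior_autoscale_error")
})

test_that("posterior summaries reduce draws as documented", {
  s <- summarize_posterior(c(-1, 0, 1, 2, 3))
  expect_equal(s$slope_median, 1)
  expect_equal(s$pr_slope_positive, 0.6)

  const <- summarize_posterior(rep(4.2, 100))
  expect_equal(const$cri$lower, 4.2)
  expect_equal(const$cri$upper, 4.2)
  expect_equal(const$pr_slope_positive, 1)

  set.seed(10)
  draws <- rnorm(2e5, mean = 7, sd = 3)
  big <- summarize_posterior(draws)
  # the 2.5th-percentile estimator's MC sd here is ~0.018, so allow ~3 sd
  expect_equal(big$cri$lower, 7 - 1.96 * 3, tolerance = 0.05)
  expect_equal(big$cri$upper, 7 + 1.96 * 3, tolerance = 0.05)
  expect_equal(big$pr_slope_positive + mean(draws <= 0), 1)

  wide <- summarize_posterior(draws, prob = 0.99)
  expect_lt(wide$cri$lower, big$cri$lower)
  expect_gt(wide$cri$upper, big$cri$upper)
})

test_that("the sampler draws the advertised number of post-warmup samples", {
  md <- quick_model_data(64)
  fit <- fit_model(md, prior_spec(), mcmc_spec(chains = 4, iterations = 1000,
                                               seed = 5))
  expect_equal(nrow(fit$pooled), 4 * 500)
  expect_true(all(c("alpha", "beta", "sigma", "sd_a", "sd_b", "rho") %in%
                    colnames(fit$pooled)))
  s <- summarize_posterior(fit)
  expect_true(s$cri$lower <= s$slope_median && s$slope_median <= s$cri$upper)
  expect_true(s$pr_slope_positive >= 0 && s$pr_slope_positive <= 1)

  one_mare <- as.data.frame(md)[md$mare_id == md$mare_id[1], ]
  expect_error(fit_model(model_data(one_mare), prior_spec(), quick_mcmc()),
               class = "model_degeneracy_error")
})

test_that("fits are reproducible under the same seed", {
  md <- quick_model_data(65)
  f1 <- fit_model(md, prior_spec(), mcmc_spec(iterations = 800, seed = 99))
  f2 <- fit_model(md, prior_spec(), mcmc_spec(iterations = 800, seed = 99))
  expect_identical(f1$pooled, f2$pooled)
})

test_that("with random effects switched off the posterior slope matches pooled OLS", {
  md <- quick_model_data(66)
  priors <- prior_spec(slope_sd = 1e4, intercept_scale = 100, re_scale = 1e-5)
  fit <- fit_model(md, priors, mcmc_spec(iterations = 4000, seed = 8))
  beta <- fit$pooled[, "beta"]
  ols <- unname(coef(lm(cortisol_pg_ml ~ pain_percent, data = md))[2])
  mcse <- sd(beta) / sqrt(min(fit_diagnostics(fit, min_ess = 1)$parameters$bulk_ess))
  expect_equal(median(beta), ols, tolerance = max(5 * mcse / abs(ols), 0.02))
})

test_that("diagnostics pass on healthy chains and fail on constructed pathologies", {
  md <- quick_model_data(67)
  fit <- fit_model(md, prior_spec(), mcmc_spec(iterations = 2000, seed = 4))
  d <- fit_diagnostics(fit, limit_rhat = 1.02, min_ess = 100)
  expect_true(d$pass)
  expect_equal(d$divergences, 0L)
  expect_true(all(d$parameters$rhat < 1.02))

  # chains from two different distributions: Rhat blows up
  set.seed(1)
  bad <- coda::mcmc.list(coda::mcmc(cbind(beta = rnorm(500, 0))),
                         coda::mcmc(cbind(beta = rnorm(500, 50))))
  db <- fit_diagnostics(bad)
  expect_gt(db$parameters$rhat, 1.5)
  expect_false(db$pass)

  # constant chains are degenerate
  const <- coda::mcmc.list(coda::mcmc(cbind(beta = rep(1, 500))),
                           coda::mcmc(cbind(beta = rep(1, 500))))
  dc <- fit_diagnostics(const)
  expect_true(is.nan(dc$parameters$rhat))
  expect_equal(dc$parameters$bulk_ess, 0)
  expect_false(dc$pass)

  expect_error(fit_diagnostics(coda::mcmc.list(coda::mcmc(cbind(beta = 1:5)))),
               class = "diagnostics_error")
})

test_that("prior predictive mass sits at plausible cortisol magnitudes", {
  md <- quick_model_data(68)
  pp <- prior_predictive(prior_spec(), md, n_sims = 1500, seed = 2)
  expect_gt(pp$central_magnitude, 50)
  expect_lt(pp$central_magnitude, 2000)

  # spread collapses toward residual noise when the structural priors vanish
  tight <- prior_predictive(prior_spec(slope_sd = 1e-6, intercept_scale = 1e-6,
                                       re_scale = 0),
                            md, n_sims = 1500, seed = 2)
  expect_lt(tight$sd_sim, pp$sd_sim / 2)

  # outcome spread grows monotonically with the slope prior SD
  sds <- vapply(c(5, 50, 500), function(s) {
    prior_predictive(prior_spec(slope_sd = s), md, n_sims = 1500,
                     seed = 6)$sd_sim
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("posterior predictive checks calibrate on self-generated data and catch misfit", {
  md <- quick_model_data(69)
  fit <- fit_model(md, prior_spec(), mcmc_spec(iterations = 2000, seed = 12))
  ppc <- posterior_predictive(fit, n_rep = 400, seed = 3)
  for (stat in c("mean", "sd", "q25", "q75")) {
    expect_gt(ppc$p_values[[stat]], 0.025)
    expect_lt(ppc$p_values[[stat]], 0.975)
  }

  # deterministic draws with sigma = 0 replicate the linear predictor exactly
  x <- c(1, 2, 3, 4, 5, 6)
  fake_data <- structure(
    data.frame(mare_id = rep(c("a", "b"), each = 3),
               pain_percent = x, cortisol_pg_ml = 10 + 2 * x),
    class = c("model_data", "data.frame"))
  pooled <- matrix(rep(c(10, 2, 0, 0, 0, 0, 0), each = 50), nrow = 50)
  colnames(pooled) <- c("alpha", "beta", "sigma", "u[1,1]", "u[2,1]",
                        "u[1,2]", "u[2,2]")
  fake_fit <- list(pooled = pooled, data = fake_data, mare_levels = c("a", "b"))
  ppc0 <- posterior_predictive(fake_fit, n_rep = 20, seed = 1)
  expect_equal(unique(ppc0$replicated[, "sd"]), sd(10 + 2 * x))
  expect_equal(unique(ppc0$replicated[, "mean"]), mean(10 + 2 * x))

  # strongly curved data under a linear model: curvature statistic flags misfit
  set.seed(30)
  xq <- rep(seq(2, 40, length.out = 12), each = 2)
  quad <- data.frame(
    mare_id = rep(c("a", "b"), times = 12),
    pain_percent = xq,
    cortisol_pg_ml = 150 + 1 * xq + 0.6 * (xq - mean(xq))^2 + rnorm(24, 0, 5))
  qfit <- fit_model(model_data(quad), prior_spec(), quick_mcmc(seed = 13))
  qppc <- posterior_predictive(qfit, n_rep = 400, seed = 4)
  expect_true(qppc$p_values[["curvature"]] < 0.01 ||
                qppc$p_values[["curvature"]] > 0.99)
})

test_that("leverage analysis removes the stated point and reports both fits", {
  co <- simulate_panel(paper_sized_params(71))
  df <- co$panel[, c("mare_id", "timestamp", "pain_percent", "cortisol_pg_ml")]
  df$pain_percent[df$mare_id == "mare_01"][1:3] <- 28
  md <- model_data(df)
  lev <- sensitivity_leverage(md, prior_spec(), quick_mcmc(seed = 9),
                              leverage_pain = 28)
  expect_equal(lev$n_removed, 3L)
  expect_equal(nrow(lev$reduced_fit$data), nrow(md) - 3L)
  expect_s3_class(lev$full, "posterior_summary")
  expect_s3_class(lev$reduced, "posterior_summary")

  expect_warning(
    noop <- sensitivity_leverage(quick_model_data(72), prior_spec(),
                                 quick_mcmc(seed = 9), leverage_pain = 99),
    class = "leverage_noop_warning")
  expect_equal(noop$n_removed, 0L)
  expect_equal(noop$full, noop$reduced)
})

test_that("the default autoscaled prior is unit-equivariant", {
  md <- quick_model_data(73)
  dp <- sensitivity_default_prior(md, quick_mcmc(seed = 10, iterations = 3000))
  expect_equal(dp$slope_prior_sd,
               2.5 * sd(md$cortisol_pg_ml) / sd(md$pain_percent))

  ng <- as.data.frame(md)
  ng$cortisol_pg_ml <- ng$cortisol_pg_ml / 1000  # report in ng/mL
  dp_ng <- sensitivity_default_prior(model_data(ng),
                                     quick_mcmc(seed = 10, iterations = 3000))
  # the posterior is exactly equivariant; the two Gibbs runs differ only by
  # Monte-Carlo noise on the median, so compare on the CrI-width scale
  width <- dp$summary$cri$upper - dp$summary$cri$lower
  expect_lt(abs(dp_ng$summary$slope_median * 1000 - dp$summary$slope_median),
            0.15 * width)
})
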