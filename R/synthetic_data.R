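#' Parameters of the synthetic postpartum cohort
#'
#' The generator emulates the statistical structure the validation
#' pipeline assumes: a handful of heavy draft mares hospitalised for 1--4
#' days after dystocia, assessed morning and evening; percentage pain
#' scores that start around 13\% (range roughly 5--28\%), drift downwards
#' day by day, and occasionally spike upwards as a complication would;
#' salivary cortisol generated from a mare-level random-intercept /
#' random-slope linear model; and triplicate assay replicates with
#' multiplicative noise at the assay's intra-assay CV of 8.7\%.
#'
#' The cortisol anchors (`alpha0`, `sigma0`, random-effect SDs) are
#' plausibility values chosen so that simulated concentrations sit in the
#' hundreds of pg/mL; they are synthetic settings, not estimates.
#'
#' @param n_mares number of mares (default 5, the validation cohort size).
#' @param days per-mare length of stay in days: a vector recycled over
#'   mares, or `NULL` to draw each stay uniformly from 1--4.
#' @param sessions_per_day assessments per day (default 2).
#' @param alpha0 population cortisol intercept, pg/mL (default 250).
#' @param beta0 population slope, pg/mL per percent pain (default 13).
#' @param tau_a,tau_b SDs of the mare random intercepts / slopes
#'   (defaults 50 pg/mL, 4 pg/mL per percent).
#' @param rho correlation between the random intercept and slope
#'   (default 0).
#' @param sigma0 residual (sample-level) SD, pg/mL (default 60).
#' @param replicate_cv intra-assay coefficient of variation of the
#'   technical replicates (default 0.087).
#' @param replicate_noise `"multiplicative"` (CV-based, the way an
#'   intra-assay CV is defined) or `"additive"` (absolute SD
#'   `replicate_cv * alpha0`).
#' @param n_replicates technical replicates per sample (default 3).
#' @param pain_start_mean,pain_start_sd first-day pain percent
#'   distribution (defaults 13, 6; truncated to 3--30).
#' @param pain_drift change in expected pain percent per day
#'   (default -1.7).
#' @param pain_noise session-level pain noise SD in percent (default 3).
#' @param spike_rate per-session probability of an escalation spike
#'   (default 0.02).
#' @param spike_size spike magnitude in percent (default 30).
#' @param n_floor_outliers,n_displaced_outliers counts of pipetting-type
#'   (< 22 pg/mL) and displaced multivariate outliers injected by
#'   [inject_outliers()] (defaults 0).
#' @param displacement displacement magnitude in normalised-MAD units of
#'   the clean cortisol values (default 10).
#' @param skip_rate per-item skip probability in simulated assessment
#'   forms (default 0).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return a validated `generative_params` list.
#' @export
generative_params <- function(n_mares = 5, days = NULL, sessions_per_day = 2,
                              alpha0 = 250, beta0 = 13, tau_a = 50,
                              tau_b = 4, rho = 0, sigma0 = 60,
                              replicate_cv = 0.087,
                              replicate_noise = c("multiplicative", "additive"),
                              n_replicates = 3, pain_start_mean = 13,
                              pain_start_sd = 6, pain_drift = -1.7,
                              pain_noise = 3, spike_rate = 0.02,
                              spike_size = 30, n_floor_outliers = 0,
                              n_displaced_outliers = 0, displacement = 10,
                              skip_rate = 0, seed = NULL) {
  replicate_noise <- match.arg(replicate_noise)
  if (n_mares < 1 || sessions_per_day < 1 || n_replicates < 1) {
    stop_with("params_validation_error", "counts must be >= 1")
  }
  if (tau_a < 0 || tau_b < 0 || sigma0 < 0 || replicate_cv < 0 ||
      pain_start_sd < 0 || pain_noise < 0) {
    stop_with("params_validation_error", "all SDs and the CV must be >= 0")
  }
  if (abs(rho) >= 1) {
    stop_with("params_validation_error", "|rho| must be < 1")
  }
  if (spike_rate < 0 || spike_rate > 1 || skip_rate < 0 || skip_rate > 1) {
    stop_with("params_validation_error", "rates must lie in [0, 1]")
  }
  if (n_floor_outliers < 0 || n_displaced_outliers < 0 || displacement < 0) {
    stop_with("params_validation_error", "outlier settings must be >= 0")
  }
  structure(
    list(n_mares = as.integer(n_mares), days = days,
         sessions_per_day = as.integer(sessions_per_day), alpha0 = alpha0,
         beta0 = beta0, tau_a = tau_a, tau_b = tau_b, rho = rho,
         sigma0 = sigma0, replicate_cv = replicate_cv,
         replicate_noise = replicate_noise,
         n_replicates = as.integer(n_replicates),
         pain_start_mean = pain_start_mean, pain_start_sd = pain_start_sd,
         pain_drift = pain_drift, pain_noise = pain_noise,
         spike_rate = spike_rate, spike_size = spike_size,
         n_floor_outliers = as.integer(n_floor_outliers),
         n_displaced_outliers = as.integer(n_displaced_outliers),
         displacement = displacement, skip_rate = skip_rate, seed = seed),
    class = "generative_params"
  )
}

# latent pain-percent trajectories: one row per mare x session
simulate_pain_trajectories <- function(params) {
  days <- params$days
  stays <- if (is.null(days)) {
    sample(1:4, params$n_mares, replace = TRUE)
  } else {
    rep_len(as.integer(days), params$n_mares)
  }
  base_date <- as.POSIXct("2026-01-01 00:00", tz = "UTC")
  session_hours <- if (params$sessions_per_day == 2) c(8, 20) else {
    round(seq(8, 20, length.out = params$sessions_per_day))
  }
  rows <- vector("list", params$n_mares)
  for (i in seq_len(params$n_mares)) {
    start <- min(max(stats::rnorm(1, params$pain_start_mean,
                                  params$pain_start_sd), 3), 30)
    recs <- list()
    for (d in seq_len(stays[i])) {
      for (s in seq_len(params$sessions_per_day)) {
        pain <- start + params$pain_drift * (d - 1) +
          stats::rnorm(1, 0, params$pain_noise)
        if (stats::runif(1) < params$spike_rate) pain <- pain + params$spike_size
        pain <- round_half_up(min(max(pain, 0.5), 100), 1)
        recs[[length(recs) + 1L]] <- data.frame(
          mare_id = sprintf("mare_%02d", i), day = d,
          session = if (session_hours[s] < 14) "morning" else "evening",
          timestamp = base_date + ((d - 1) * 24 + session_hours[s]) * 3600,
          pain_percent = pain, stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  do.call(rbind, rows)
}

#' Simulate a cortisol replicate panel
#'
#' Draws per-mare random intercepts and slopes from their bivariate
#' normal distribution, generates pain trajectories, forms sample-level
#' cortisol means `mu = (alpha0 + a_i) + (beta0 + b_i) * pain + N(0,
#' sigma0)`, and expands each sample into technical replicates with
#' multiplicative noise `y = mu * (1 + N(0, CV))`.  Deterministic under
#' `params$seed`.
#'
#' @param params a [generative_params()].
#' @return a `synthetic_cohort`: `params`, `effects` (realised per-mare
#'   `(a, b)`), `panel` (replicate-level data.frame with `mare_id`, `day`,
#'   `session`, `timestamp`, `pain_percent`, `replicate_index`,
#'   `cortisol_pg_ml`, `outlier_type`), and `clean_panel` (identical until
#'   [inject_outliers()] contaminates `panel`).
#' @export
simulate_panel <- function(params = generative_params()) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  Sigma <- matrix(c(params$tau_a^2,
                    params$rho * params$tau_a * params$tau_b,
                    params$rho * params$tau_a * params$tau_b,
                    params$tau_b^2), 2, 2)
  eff <- MASS::mvrnorm(params$n_mares, c(0, 0), Sigma)
  eff <- matrix(eff, ncol = 2)
  effects <- data.frame(mare_id = sprintf("mare_%02d", seq_len(params$n_mares)),
                        a = eff[, 1], b = eff[, 2], stringsAsFactors = FALSE)
  traj <- simulate_pain_trajectories(params)
  rows <- vector("list", nrow(traj))
  for (r in seq_len(nrow(traj))) {
    i <- match(traj$mare_id[r], effects$mare_id)
    mu <- (params$alpha0 + effects$a[i]) +
      (params$beta0 + effects$b[i]) * traj$pain_percent[r] +
      stats::rnorm(1, 0, params$sigma0)
    mu <- max(mu, 25)  # cortisol means are strictly positive and above the QC floor
    noise <- stats::rnorm(params$n_replicates, 0, params$replicate_cv)
    y <- if (params$replicate_noise == "multiplicative") {
      mu * (1 + noise)
    } else {
      mu + noise / max(params$replicate_cv, 1e-12) *
        (params$replicate_cv * params$alpha0)
    }
    y <- pmax(y, 0.5)
    rows[[r]] <- data.frame(
      traj[r, , drop = FALSE], replicate_index = seq_len(params$n_replicates),
      cortisol_pg_ml = y, true_mean = mu, outlier_type = "none",
      row.names = NULL, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  structure(list(params = params, effects = effects, panel = panel,
                 clean_panel = panel),
            class = "synthetic_cohort")
}

#' Inject assay outliers into a synthetic panel
#'
#' Contaminates a cohort with the two artefact types the QC pipeline must
#' catch: pipetting-type failures (replicate values replaced by draws
#' below the 22 pg/mL floor) and displaced multivariate outliers
#' (cortisol shifted upwards by `displacement` normalised MADs of the
#' clean cortisol distribution).  Ground-truth labels are recorded in
#' `outlier_type`; `clean_panel` keeps the uncontaminated data.
#'
#' @param cohort a `synthetic_cohort` from [simulate_panel()].
#' @param params a [generative_params()] supplying the outlier settings
#'   (defaults to the cohort's own).
#' @return the cohort with a contaminated `panel`.
#' @export
inject_outliers <- function(cohort, params = cohort$params) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n_floor <- params$n_floor_outliers
  n_disp <- params$n_displaced_outliers
  panel <- cohort$clean_panel
  total <- n_floor + n_disp
  if (total == 0L) {
    cohort$panel <- panel
    return(cohort)
  }
  if (total > nrow(panel)) {
    stop_with("contamination_error",
              "cannot contaminate %d of %d replicates", total, nrow(panel))
  }
  idx <- sample.int(nrow(panel), total)
  floor_idx <- idx[seq_len(n_floor)]
  disp_idx <- idx[setdiff(seq_len(total), seq_len(n_floor))]
  if (n_floor > 0L) {
    panel$cortisol_pg_ml[floor_idx] <- stats::runif(n_floor, 5, 21.5)
    panel$outlier_type[floor_idx] <- "floor"
  }
  if (n_disp > 0L) {
    scale_ <- stats::mad(cohort$clean_panel$cortisol_pg_ml)
    panel$cortisol_pg_ml[disp_idx] <- panel$cortisol_pg_ml[disp_idx] +
      params$displacement * scale_
    panel$outlier_type[disp_idx] <- "displaced"
  }
  cohort$panel <- panel
  cohort
}

# distribute target_points over the non-skipped items of the scale,
# moving along each item's allowed-point ladder until the residual cannot
# be reduced further (granularity 0.5 on the bundled instrument)
allocate_points <- function(target_percent, scale, skipped = character()) {
  if (target_percent < 0 || target_percent > 100) {
    stop_with("target_validation_error",
              "target percent %g outside [0, 100]", target_percent)
  }
  items <- scale_items(scale)
  active <- items[!items$item_id %in% skipped, , drop = FALSE]
  adj_max <- scale_maximum(scale, skipped)
  target_points <- round(target_percent / 100 * adj_max * 2) / 2
  assigned <- stats::setNames(numeric(nrow(active)), active$item_id)
  rem <- target_points
  for (i in sample(seq_len(nrow(active)))) {
    allowed <- active$allowed_points[[i]]
    ok <- allowed[allowed <= rem + 1e-9]
    val <- if (length(ok)) max(ok) else 0
    assigned[active$item_id[i]] <- val
    rem <- rem - val
  }
  # repair pass: single-step moves along allowed ladders while they shrink |rem|
  repeat {
    if (abs(rem) < 1e-9) break
    best <- NULL; best_gain <- abs(rem) - 1e-9
    for (i in seq_len(nrow(active))) {
      allowed <- active$allowed_points[[i]]
      cur <- assigned[active$item_id[i]]
      pos <- which(abs(allowed - cur) < 1e-9)
      for (step in c(pos - 1L, pos + 1L)) {
        if (step < 1L || step > length(allowed)) next
        delta <- allowed[step] - cur
        if (abs(rem - delta) < best_gain) {
          best_gain <- abs(rem - delta)
          best <- c(i, allowed[step], delta)
        }
      }
    }
    if (is.null(best)) break
    assigned[active$item_id[best[1]]] <- best[2]
    rem <- rem - best[3]
  }
  assigned
}

#' Simulate item-level assessment forms
#'
#' Maps latent pain-percent targets to complete item-level responses on
#' the instrument: points are distributed over the items so that the
#' scored percentage lands within a fraction of a point of the target,
#' with optional item skips.  Closing the loop through
#' [score_assessment()] recovers the target percentages.
#'
#' @param params a [generative_params()] (supplies trajectories, the skip
#'   rate, and the seed).
#' @param scale a `scale_definition`.
#' @param targets optional data.frame (`mare_id`, `timestamp`,
#'   `pain_percent`) of targets to hit; defaults to freshly simulated
#'   trajectories.
#' @return list with `assessments` (a list of [assessment()] objects) and
#'   `targets` (the targets used).
#' @export
simulate_assessments <- function(params = generative_params(),
                                 scale = bundled_scale(), targets = NULL) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.null(params$seed)) set.seed(params$seed + 1L)
  if (is.null(targets)) {
    targets <- simulate_pain_trajectories(params)
  }
  items <- scale_items(scale)
  assessments <- vector("list", nrow(targets))
  for (r in seq_len(nrow(targets))) {
    skipped <- character()
    if (params$skip_rate > 0) {
      cand <- items$item_id[items$skippable]
      skipped <- cand[stats::runif(length(cand)) < params$skip_rate]
      if (length(skipped) == nrow(items)) skipped <- skipped[-1]
    }
    pts <- allocate_points(targets$pain_percent[r], scale, skipped)
    assessments[[r]] <- assessment(
      mare_id = targets$mare_id[r], timestamp = targets$timestamp[r],
      points = pts, skipped = skipped)
  }
  list(assessments = assessments, targets = targets)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_cohort> %d mares, %d replicate rows (beta0 = %g pg/mL per %%)\n",
              p$n_mares, nrow(x$panel), p$beta0))
  n_out <- sum(x$panel$outlier_type != "none")
  if (n_out) cat(sprintf("  contaminated: %d labelled outlier(s)\n", n_out))
  invisible(x)
}
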