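---
title: "Scoring postpartum pain in mares and validating it against salivary cortisol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring postpartum pain in mares and validating it against salivary cortisol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marepain)
```

`marepain` does two connected jobs. It scores a composite behavioural pain
scale for mares in the days after foaling — eight examination blocks, 25
items, 47 points in total — with the skip-adjusted percentage normalisation
that keeps scores comparable when parts of the examination are unsafe to
perform. And it implements the physiological validation pipeline that anchors
those scores to salivary cortisol: technical-replicate quality control, a
Bayesian linear mixed model of cortisol on pain score with per-mare random
intercepts and slopes, predictive checks, convergence diagnostics, and two
sensitivity analyses. A synthetic-cohort generator with known ground truth
lets the entire pipeline be exercised and tested without clinical data.

## The instrument and skip-adjusted scoring

The instrument lives in a versioned JSON document
(`inst/extdata/postpartum_mare_scale_v1.json`), loaded and validated by
`load_scale()`; `bundled_scale()` returns the packaged definition. Items
carry explicit sets of permitted point values. Many are sparse — "mare's
interest in her abdomen/vulvar area" admits only 0, 2 or 4; tail carriage,
vocalisation and sweating only 0 or 1; each of the four hoof-temperature
items only 0 or 0.5 — and the scorer rejects any value outside an item's
set. Part and total maxima are always recomputed from the items; maxima
stored in a document are cross-checked declarations, so a hand-edited file
that no longer adds up is refused with an integrity error.

All point values are multiples of 0.5, which are exactly representable in
floating point, so totals accumulate without drift and need no decimal
arithmetic layer.

When items cannot be scored (an uncooperative or dangerous mare), they are
skipped rather than scored zero. The maximum attainable score drops by the
skipped items' maxima (`scale_maximum()`), and the percentage score is
computed against this *adjusted maximum*. Skipping a whole examination block
means skipping all its items; skipping the two palpation blocks (parts 4
and 6) reduces the maximum from 47 to 42, and a mare scoring 16 of those 42
points reports 100·16/42 = 38.1%.

```{r skip-example}
sc <- bundled_scale()
it <- scale_items(sc)
scale_maximum(sc, it$item_id[it$part_id %in% c(4, 6)])
round_half_up(100 * 16 / 42, 1)
```

Two reporting choices are deliberate and configurable:

* **Rounding.** Percentages are reported to one decimal, rounded half
  *up* (`round_half_up()`), the convention of clinical report forms; base
  R's round-half-to-even would turn 38.05 into 38.0. The printed precision
  is also what `classify()` operates on, so the reported number and the
  decision never disagree.
* **The 40% boundary.** Scores *above* 40% indicate analgesic treatment,
  scores *below* 40% minimal-to-no discomfort. Exactly 40% is not covered
  by that rule; the default policy maps it to `"minimal-to-none"` (strict
  `>`), with `boundary_policy = "treat"` as the alternative, and the
  command-line tools print which rule is in force.

`build_trajectory()` orders one mare's assessments in time and raises an
escalation flag when the percentage rises across consecutive assessments or
crosses the threshold — serial scoring is the intended use, since persistent
or rising scores are what signal postpartum complications.

## Replicate quality control

Salivary cortisol is assayed in technical triplicates. Before modelling,
replicates pass a three-stage, single-pass screen (`run_qc()`):

1. **Absolute floor.** Readings strictly below 22 pg/mL are flagged as
   pipetting-type failures (`floor_filter()`). The inequality is strict:
   exactly 22.0 is retained.
2. **Projection outlier screen.** `projection_outliers()` implements a
   projection-depth rule: centre the data at the coordinate-wise median;
   for each observation, project all points onto the direction from the
   centre through that observation; standardise each projection by its
   median and normalised MAD (MAD/0.6745); flag a point if its absolute
   robust z-score exceeds `sqrt(qchisq(0.975, p))` in *any* projection.
   The default feature space is the (pain percent, cortisol) pair of each
   replicate — the plane in which the model operates — and is
   configurable. Projections with zero MAD (degenerate directions) are
   skipped with a warning. The screen runs once, not iteratively: the
   flagged set is removed and the survivors are not re-screened.
3. **Replicate-count enforcement.** Every mare × sampling-time must keep at
   least two replicates (`enforce_replicates()`); samples below the minimum
   are listed as failures and excluded from the model with a warning.

Numerical notes. The cutoff quantile is `1 - alpha` with `alpha = 0.025`
per side — the documented default of the projection-method family. The
screen is deterministic given the data, and invariant to translations,
a common scale factor and axis reflections (similarity transforms preserve
the data-driven direction set, and scale cancels inside each robust
z-score). It is *not* invariant to anisotropic axis rescaling, which
changes the direction set; this matters if you screen on features with
wildly different units, which is intended — the screen sees the same
geometry the analyst plots. By construction the rule tolerates a
false-alarm probability of roughly `2*alpha` per point on clean Gaussian
data, so on a ~40-replicate panel one or two spurious flags are
statistically expected every few runs; the QC report always states which
points were removed and why, and removal decisions should be reviewed, not
automated away.

## The validation model

The model for retained replicates is a Gaussian linear mixed model,

$$y_{ij} = (\alpha + a_i) + (\beta + b_i)\,x_{ij} + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma^2),
\qquad (a_i, b_i) \sim \mathcal N_2(0, \Sigma),$$

with $y$ the cortisol concentration in pg/mL, $x$ the percentage pain
score, and $i$ indexing mares — the only grouping factor. Observations
enter at replicate level by default (each retained replicate is one row);
`model_data(..., aggregate = "mean")` offers sample means instead. The
outcome is untransformed: over the observed score range the association is
approximately linear with roughly symmetric residuals, and no circadian
terms are included. For cohorts spanning a wider score range a
log-outcome analysis is likely more appropriate for strictly positive,
right-skewed concentrations; model the log of `cortisol_pg_ml` directly in
that case.

### Priors

* **Slope** (the scientifically loaded prior): $\beta \sim \mathcal N(0,
  29.63^2)$ pg/mL per percentage point. The scale encodes "a shift of up
  to two outcome SDs per one SD of pain score is fairly likely, smaller
  shifts more likely than larger, either sign equally likely";
  `compute_slope_prior_sd()` reproduces the construction
  ($2\,\mathrm{SD}(y)/\mathrm{SD}(x)$ on the cleaned analysis data, which
  evaluates to 29.63 on the published cohort) for any dataset.
* **Intercept**: $\mathcal N(\bar y, (2.5\,\mathrm{SD}(y))^2)$, placed on
  the intercept at the mean pain score (the covariate is centred
  internally — the convention of the major Bayesian regression packages).
* **Residual SD**: Exponential with mean $\mathrm{SD}(y)$.
* **Random-effect covariance**: a trace-decomposition prior. Total scale
  $\tau \sim \mathrm{Gamma}(2, 2)$; the variance split across
  intercept/slope components follows a $\mathrm{Dirichlet}(2, 2)$; the
  correlation follows $2\,\mathrm{Beta}(2, 2) - 1$, the exact 2×2 LKJ
  density with shape 2. All four constants default to 2 rather than the
  flat 1: with five mares the covariance is weakly identified, and mild
  regularisation stabilises computation without noticeably moving the
  slope — the standard recommendation when the number of groups is small.
  Reference scales are $\mathrm{SD}(y)$ for intercepts and
  $\mathrm{SD}(y)/\mathrm{SD}(x)$ for slopes.

`prior_spec(mode = "default_autoscaled")` swaps the slope prior for the
conventional autoscaled default $\mathcal N(0, (2.5\,\mathrm{SD}(y)/
\mathrm{SD}(x))^2)$, used by the prior-sensitivity analysis.

### Sampling and parameterisation

`fit_model()` samples by Gibbs sampling (JAGS), four chains of 20,000
iterations each with the first half as warmup by default, seeds derived
deterministically per chain from the single `mcmc_spec()` seed. The model
is coded with a centred covariate and *hierarchically centred* mare
coefficients, $v_i \sim \mathcal N_2((\alpha_c, \beta), \Sigma)$: the
posterior correlation between the population slope and the slope deviations
otherwise throttles the Gibbs sampler (split-Rhat for $\beta$ stalls around
1.02 at full length; with centring it reaches ~1.001 with bulk ESS in the
thousands). Raw-scale intercept and deviations are recovered as derived
quantities.

Hierarchical centring has a known failure mode in the opposite regime:
as the random-effect scale is forced toward zero the mare coefficients pin
to the population values and the update degenerates into a frozen random
walk. `prior_spec(re_scale = ...)` therefore switches to an explicit pooled
regression (no mare-level block) below `re_scale = 1e-3`, taking the limit
analytically instead of numerically. That pooled limit is also a test
oracle: with a near-flat slope prior it must agree with ordinary least
squares on the pooled data to within Monte-Carlo error, and does.

### Summaries, diagnostics, predictive checks

`summarize_posterior()` reports the posterior median of the slope, the
direction probability $\Pr(\beta > 0)$ as the fraction of positive draws,
and the 95% equal-tailed credible interval (2.5th–97.5th percentiles).

`fit_diagnostics()` computes rank-normalised split-Rhat and bulk effective
sample size per parameter, passing at the community defaults Rhat ≤ 1.01
and bulk ESS ≥ 400 (both configurable). The divergence count it reports is
structurally zero: divergent transitions are a Hamiltonian-Monte-Carlo
diagnostic and the Gibbs sampler has no analogue, so convergence rests on
Rhat, ESS and the predictive checks. Constant (degenerate) chains report
`Rhat = NaN`, `ESS = 0` and fail.

`prior_predictive()` simulates full parameter sets from the prior and
outcomes over the observed pain scores; with the default priors the
central simulated magnitudes sit in the hundreds of pg/mL — physiologically
plausible for equine salivary cortisol — rather than at absurd scales.
`posterior_predictive()` draws replicated datasets from the fit and
compares observed mean, SD, quartiles and a curvature statistic (the
correlation of residuals with the squared centred pain score, sensitive to
a nonlinear trend a linear model would miss) against their replicated
distributions, reporting tail probabilities.

### Sensitivity analyses

`sensitivity_leverage()` removes every observation at a stated pain score —
by default 28, the kind of isolated high score that can dominate a fitted
slope in a small cohort — refits with unchanged priors, and reports the
full-data and reduced-data summaries side by side.
`sensitivity_default_prior()` refits all data under the autoscaled default
slope prior. Neither analysis should move the qualitative conclusion if the
association is real; both are part of `run_validation()`'s standard output.

## The synthetic cohort generator

`generative_params()` + `simulate_panel()` emulate the study conditions:
five mares hospitalised 1–4 days after dystocia, assessed at 08:00 and
20:00; first-day pain scores around 13% (spread 6, truncated to 3–30%),
drifting −1.7 percentage points per day with 3-point session noise and a
2% chance of a +30-point escalation spike (mirroring day-wise cohort means
of roughly 13, 12, 9, 8% and the occasional mare that escalates toward
47%); cortisol from the mixed model above with $\alpha_0 = 250$ pg/mL,
$\beta_0 = 13$ pg/mL per percent, $\tau_a = 50$, $\tau_b = 4$, $\rho = 0$,
$\sigma_0 = 60$; and triplicate replicates with multiplicative noise at the
assay's 8.7% intra-assay CV (an additive mode exists, but a CV is by
definition multiplicative). The cortisol anchors are plausibility values
chosen once so that simulated concentrations sit in the hundreds of pg/mL
with $\mathrm{SD}(y)$ near 100–120; they are synthetic settings, not
estimates of any real cohort.

`simulate_assessments()` closes the loop at item level: a target
percentage is converted into a complete instrument form by walking points
onto the items' allowed-value ladders (greedy allocation in random order,
then single-step repair moves until the residual cannot shrink further).
On the bundled instrument any half-point total is reachable, so scoring
the generated form recovers the target to within about one percentage
point. `inject_outliers()` contaminates a panel with labelled
pipetting-type values (uniform 5–21.5 pg/mL, below the floor by
construction) and displaced points (cortisol shifted by 10 normalised MADs),
keeping the clean panel alongside for oracle comparisons.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: assay plate and standard-curve effects,
circadian cortisol structure, informative discharge (stays are independent
of simulated pain), inter-rater disagreement, and any nonlinearity or
heteroskedasticity in the pain–cortisol relationship. The generator is a
test of the pipeline's statistical machinery under its own assumptions,
not evidence about mares.

## Verification approach and problem sizes

The test suite checks scoring against brute-force re-summation (200 random
forms and an exhaustive enumeration on a reduced two-part instrument), the
projection screen against a loop-based oracle that enumerates every
point-through-centre direction independently, posterior summaries against
closed-form quantiles, the pooled limit against least squares, and the
full pipeline in closed loop: across twenty synthetic cohorts at study
size (five mares, ~14 sampling times, triplicates, reduced chains of
4 × 2,000 iterations), the 95% credible interval covers the generating
slope in well over 85% of runs. Two honest caveats from the same
experiments: under a null slope the direction probability
$\Pr(\beta > 0)$ is approximately uniform across cohorts — as it must be
for a near-calibrated posterior — so no central band can contain it for
most seeds; and the projection screen's designed ~2.5% per-point false
alarm rate means contamination recovery is "all injected outliers caught,
occasionally one extra sample flagged", not exact-set recovery. Both
behaviours are properties of the methods, not defects of the
implementation, and the corresponding checks document them.

## Limitations

The engine inherits the instrument's own preliminary status: a small,
single-breed, single-complication validation cohort, no pain-free control
group, consensus rather than independent ratings, and cortisol's
non-specificity as a stress marker. Nothing in this package strengthens
those evidential limits; it makes the scoring and the validation analysis
reproducible, configurable and testable so that larger cohorts can be
analysed the same way.
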