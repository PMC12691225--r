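# marepain

Scoring and physiological validation for a composite pain scale for
postpartum mares.

Mares can be in substantial pain in the days after foaling, especially
after dystocia, and no dedicated instrument existed for that context.
`marepain` implements such an instrument as software, for veterinarians,
clinical researchers and biostatisticians: an eight-part, 47-point
behavioural and clinical examination (stall observation, facial
expression / Horse Grimace Scale, clinical examination, mammary and torso
palpation, peristalsis, hoof temperature, food test, walking traits),
scored item by item, normalised as a percentage of a *skip-adjusted*
maximum so that scores stay comparable when parts of the examination are
unsafe to perform, and classified against a 40% analgesia threshold.

It also implements the validation analysis that anchors the scale to
salivary cortisol, a non-invasive physiological stress marker. After
technical-replicate quality control (an absolute <22 pg/mL floor filter
and a projection-based robust multivariate outlier screen), retained
replicates enter a Bayesian linear mixed model

```
y_ij = (α + a_i) + (β + b_i)·x_ij + ε_ij,   ε_ij ~ N(0, σ²),
(a_i, b_i) ~ N₂(0, Σ)
```

with `y` salivary cortisol (pg/mL), `x` the percentage pain score, and
random intercepts `a_i` and slopes `b_i` per mare. The slope prior is
weakly informative, `β ~ N(0, 29.63²)` pg/mL per percentage point (a shift
of up to two outcome SDs per SD of pain score is plausible); fitting is by
MCMC (4 chains × 20,000 iterations, 50% warmup, via JAGS), and results are
reported as the posterior median slope, `Pr(β > 0)`, and the 95%
equal-tailed credible interval, alongside rank-normalised split-Rhat /
bulk-ESS diagnostics, prior and posterior predictive checks, and two
sensitivity analyses (leverage-point removal, default autoscaled prior).
A synthetic-cohort generator with known ground truth makes the entire
pipeline testable without clinical data.

## Worked example

Score a single assessment on the bundled instrument — a mare whose
palpation blocks (parts 4 and 6) had to be skipped, so her 16 points are
judged against an adjusted maximum of 42:

```r
library(marepain)
sc <- bundled_scale()
it <- scale_items(sc)
palpation <- it$item_id[it$part_id %in% c(4, 6)]

a <- assessment("nadzieja", "2026-03-02 08:00",
                points = c(posture_weight = 3, body_position = 2,
                           abdomen_interest = 4, surroundings_response = 2,
                           head_wrinkles = 2, ear_position = 1,
                           eyelids = 1, respiratory_rate = 1),
                skipped = palpation, scale = sc, fill_zero = TRUE)
score_assessment(a, sc)
#> <score_result> mare nadzieja @ 2026-03-02 08:00 (morning)
#>   total 16 / 42 points (7 item(s) skipped)
#>   pain score: 38.1% -> minimal-to-none
```

38.1% is 100·16/42 rounded half-up to one decimal; it sits below the 40%
threshold, so no analgesia is indicated — though a strict reading: exactly
40.0% also classifies as `minimal-to-none` by default
(`boundary_policy = "treat"` flips that).

Run the full cortisol validation pipeline on a synthetic cohort at study
conditions (5 mares, triplicate assays, generating slope 13 pg/mL per
percent, with 2 pipetting-type and 2 displaced outliers injected):

```r
params <- generative_params(seed = 1, days = c(1, 1, 2, 2, 1),
                            n_floor_outliers = 2, n_displaced_outliers = 2)
cohort <- inject_outliers(simulate_panel(params))
report <- run_validation(list(
  cortisol = cohort$panel[, c("mare_id", "timestamp", "replicate_index",
                              "cortisol_pg_ml", "pain_percent")],
  leverage_pain = max(cohort$panel$pain_percent),
  seed = 1))
#> [validate] 42 replicate rows loaded
#> [validate] QC: 2 floor-removed, 2 projection-removed, 38 retained
#> [validate] fitting on 38 observations from 5 mares (seed 1)
#> [validate] slope 17.52 (CrI -1.27..32.16); leverage-removed 18.18; default-prior 18.86
```

The QC stage recovered exactly the four injected artefacts. The posterior
median slope of 17.52 pg/mL per percentage point estimates the generating
value of 13 from 38 observations of five mares — the credible interval
(−1.27 to 32.16) covers it, and its width is what five mares buy you. The
two sensitivity fits barely move the estimate, and the diagnostics are
clean:

```r
report$diagnostics
#> <mcmc_diagnostics>
#>   divergences: 0
#>   max Rhat: 1.0017 (limit 1.010); min bulk ESS: 3030 (min 400)
#>   pass: TRUE
```

A command-line front end (`inst/cli/marepain.R`) exposes the same
functionality as `score`, `batch`, `qc`, `fit`, `simulate` and `validate`
subcommands; `validate --config run.json` is the one-shot path from CSV
files to a full report directory.

## Repository layout

- `R/`, `inst/extdata/postpartum_mare_scale_v1.json` — implementation and
  the bundled instrument definition
- `inst/cli/marepain.R` — command-line front end
- `vignettes/cortisol-validation-methods.Rmd` — the methods vignette: model,
  priors, QC rules, generator assumptions, numerical choices, limitations
- `tests/testthat/` — unit, property and acceptance tests
- `scripts/acceptance.R` — end-to-end reproduction script
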