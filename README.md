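# mortboot

Do richer mortality models actually change the *forecasts* of the
indicators demographers and actuaries care about?  `mortboot` implements
a complete, tested pipeline for answering that question on an
age-by-year surface of death probabilities:

* **Models.**  Three Lee-Carter-family models on the logit of the death
  probability, fitted by quasi-binomial maximum likelihood:
  `LC1` (logit q<sub>xt</sub> = a<sub>x</sub> + b<sub>x</sub> k<sub>t</sub>),
  `LC2` (a second bilinear age-period term), and
  `H1` (a cohort effect γ<sub>t−x</sub>, fitted in two stages with the
  intercepts fixed at year-mean logits and the first/last five cohorts
  down-weighted to zero).
* **Indicators.**  Period life tables per forecast year give life
  expectancy at birth and at 65, the modal age at death (ages above 5),
  and the Gini index of lifespan inequality from the discrete Lorenz
  curve (ratio of Σ(f−g) to Σf over ages 0..ω−1).
* **Uncertainty.**  A two-dimensional residual block bootstrap: deviance
  residuals are resampled in non-overlapping rectangular blocks
  (preserving age-period dependence), inverted back to death counts
  through the deviance equation, and every model is refit on every
  resample; period/cohort indices are projected with ARIMA processes
  (orders fixed at the original fit, coefficients refit per replicate)
  and 95% percentile intervals are read off the replicate curves.
* **Comparison.**  The 3 fitting models x 3 residual sources design is
  tested with a random-projection functional ANOVA: each replicate curve
  is projected on K = 30 Brownian directions, a balanced two-way ANOVA
  runs per direction, and p-values are combined by the
  false-discovery-rate rule min(1, min<sub>i</sub> K p<sub>(i)</sub>/i),
  plus pairwise level comparisons.
* **Synthetic data.**  `make_params()`/`simulate_deaths()` generate
  surfaces with known Lee-Carter/cohort structure (binomial or
  beta-binomial counts), so everything is testable without external
  data.

The methods vignette (`vignettes/mortality-model-comparison.Rmd`)
documents the model, every numerical choice, and the design decisions.

## Worked example

```r
library(mortboot)

params  <- make_params(A = 90, T = 20, family = "LC1", seed = 2024)
surface <- simulate_deaths(params, exposure = 1e5, seed = 2025)
surface
#> Mortality surface: 90 ages (0..89) x 20 years (1991..2010)

fit <- fit_lc(surface, r = 1)
fit
#> LC1 fit: 90 ages x 20 years, deviance 1592, dispersion 0.993

run <- run_experiment(surface, n_boot = 10, horizon = 20, seed = 1)
run
#> Crossed mortality experiment: 3 models x 3 sources, N = 10, horizon 20
#>   e0     model R, sample R, interaction R
#>   e65    model R, sample R, interaction R
#>   modal  model NR, sample NR, interaction NR
#>   gini   model R, sample R, interaction R
```

The fit's deviance (1592 on 1800 cells with 200 parameters, dispersion
0.99) says the one-term model describes its own simulated data with no
overdispersion.  The experiment's summary prints one reject/non-reject
triple per indicator: here the fitting model, the residual source and
their interaction all shift the life-expectancy and Gini forecast
curves, while the integer-valued modal age barely moves at this scale.

Percentile intervals per design cell:

```r
subset(run$intervals, indicator == "e0" & model == "LC1" & residual_source == "LC1")
#>   year lower upper
#> 1 2011 79.46 79.55
#> 2 2012 79.50 79.59
#> ...
#> 20 2030 80.18 80.34
```

Life expectancy at birth rises by about 0.8 years over the horizon and
the interval widens from 0.09 to 0.16 years as parameter error
accumulates through the random-walk drift.  Per-indicator detail:

```r
run$fanova$gini
#> Functional ANOVA (gini), K = 30, alpha = 0.05
#>   model:       p = 9.292e-07 [R]
#>   sample:      p = 6.479e-24 [R]
#>   interaction: p = 1.401e-07 [R]

run$pairwise$gini$model
#>   level1 level2           p  p_adjusted decision
#> 1    LC1    LC2 0.999745074 0.999745074       NR
#> 2    LC1     H1 0.001508102 0.002580317        R
#> 3    LC2     H1 0.001720212 0.002580317        R
```

The pairwise table pins the Gini model effect on the cohort model: the
two pure age-period models forecast indistinguishable inequality paths,
while `H1` differs from both.

## The analysis workflow

`analysis/` holds the study as numbered drivers over the package
(regenerate everything under `results/`):

```sh
Rscript analysis/01_simulate_surface.R    # synthetic study surface (CSV)
Rscript analysis/02_fit_models.R          # LC1/LC2/H1 deviance table, fits as JSON
Rscript analysis/03_bootstrap_experiment.R  # N = 50 crossed bootstrap, curves + intervals
Rscript analysis/04_fanova.R              # decision tables, pairwise comparisons
```

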