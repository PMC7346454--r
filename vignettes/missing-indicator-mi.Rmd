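---
title: "Missing indicators with multiple imputation: models, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing indicators with multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimisim)
```

## The problem

In routinely collected health data, whether a value is recorded is itself
informative: a laboratory test is ordered for a reason, and that reason may
be an unrecorded patient characteristic that also affects the outcome. When
the exposure of interest is the partially missing variable, the missingness
indicator can act as a *proxy* for such an unmeasured confounder. The
question this package studies by Monte Carlo simulation is when adding a
missing-indicator term (and its interaction with the imputed exposure) to a
multiply-imputed analysis — the MIMI strategy — reduces bias in *causal*
effect estimation, relative to complete-case analysis and to standard
multiple imputation, and when it makes things worse.

Note the estimand: not the completed-data regression coefficient that the
missing-data literature usually targets, but the unconditional causal effect
of the exposure, which may be unidentifiable even with complete data when
confounding is unmeasured.

## Structural models

One simulation cell is described by a `scenario_config`. The four variables
are generated in causal order:

* $U \sim \mathrm{Bernoulli}(\pi_U)$ — a binary covariate, observed or
  unobserved depending on the analysis variant;
* $A \mid U \sim N(\alpha_0 + \alpha_U U,\ \sigma_A^2)$ — the continuous
  exposure;
* $R_A \in \{0, 1\}$ — the missingness indicator for $A$, with $R_A = 0$
  meaning missing, following either the logistic law
  $P(R_A = 0) = \mathrm{expit}(\beta_0 + \beta_U U + \beta_A A + \beta_{UA} U A)$
  or the deterministic extreme $R_A = 1 - U$;
* $Y \mid U, A \sim N(\gamma_0 + \gamma_U U + \gamma_A A + \gamma_{UA} U A,\ \sigma_Y^2)$.

The observed exposure is $A^\ast = A$ where $R_A = 1$ and missing otherwise.
Because datasets also carry the missing indicator $M = 1 - R_A$ as an
explicit column, the outcome models below never need to negate $R_A$ inline;
this removes a classic sign-error trap.

Six DAG scenarios index which edges exist: $U \to R_A$, $A \to R_A$ and the
confounding edge $U \to A$. `classify_scenario()` recovers the label from
the zero-pattern of $(\alpha_U, \beta_U, \beta_A, \beta_{UA})$ and the
deterministic flag, and `validate_scenario_config()` enforces consistency.
Two parameter patterns do not appear as separate DAG panels — confounding
with fully random missingness, and exposure-driven missingness with
confounding but no $U \to R_A$ edge. We assign them the nearest label with
the same confounding structure, (iii) and (vi) respectively; the grid
summaries key on the stored parameters as well, so this is purely a display
convention.

### Solved intercepts

The three intercepts are not free parameters. $\alpha_0 = -\alpha_U \pi_U$
centres the exposure at $E[A] = 0$; $\gamma_0$ centres the outcome using
$E[UA] = \pi_U(\alpha_0 + \alpha_U)$; and $\beta_0$ is solved so that the
*marginal* missingness probability hits its target. That marginal
probability is a two-component mixture (over the $U$ strata) of
one-dimensional Gaussian integrals of the expit function. We evaluate each
integral with 64-node Gauss–Hermite quadrature and root-find $\beta_0$ on
$[-40, 40]$ with a $10^{-6}$ tolerance on the achieved probability — a
deterministic calibration, in contrast to a stochastic Monte Carlo one,
so that configuration construction is exactly reproducible. 64 nodes is far
beyond what the smooth expit integrand needs at the slope magnitudes in the
study grid; the accuracy check is part of config validation.

Under the deterministic law $R_A = 1 - U$ the $\beta$ parameters are
redundant and the constructor refuses them; the marginal missingness is
necessarily $\pi_U$, which is why the deterministic stratum of the grid
varies $\pi_U$ instead.

## Analysis methods

For each generated dataset, up to seven outcome analyses are run, in a
U-hidden and/or a U-observed variant:

| label | model (U hidden) | U observed adds |
|---|---|---|
| CC | $Y \sim A^\ast$ on rows with $R_A = 1$ | $+\,U + U\!:\!A^\ast$ |
| MI(A) | $Y \sim A_{\mathrm{imp}}$ | $+\,U + U\!:\!A_{\mathrm{imp}}$ |
| MI(R+A) | $Y \sim A_{\mathrm{imp}} + M$ | $+\,U + U\!:\!A_{\mathrm{imp}}$ |
| MI(R\*A) | $Y \sim A_{\mathrm{imp}} + M + A_{\mathrm{imp}}\!:\!M$ | $+\,U + U\!:\!A_{\mathrm{imp}}$ |
| CD | $Y \sim A$ (completed data, ground truth) | $+\,U + U\!:\!A$ |

We parameterise the indicator main effect as $M = 1 - R_A$ in **both** MIMI
models. Writing the interaction model with an $R_A$ main effect instead
spans the same column space and yields the identical fit up to a sign flip
of that one coefficient; using $M$ throughout lets summaries align the
indicator coefficient across models.

The imputation model for the missing exposure is linear: $A$ on $Y$ when $U$
is hidden, and $A$ on $Y$, $U$ and $U Y$ (interaction always included) when
$U$ is observed. With a single incomplete variable this conditional
regression coincides with a joint-normal specification, so we implement the
conditional form directly. Imputation is *proper* in the canonical Bayesian
sense under the standard noninformative prior: per imputation, draw
$\sigma^2$ from its scaled inverse-$\chi^2$ posterior on the residual df,
draw coefficients from $N(\hat\phi,\ \sigma^2 (X^\top X)^{-1})$, then draw
each missing value from the normal predictive distribution. Five
imputations per replicate is the default, chosen for computational cost;
`m` is configurable everywhere.

Pooling follows Rubin's rules: pooled estimate $\bar Q$, within-imputation
variance $W$, between-imputation variance $B$, total $T = W + (1 + 1/m)B$.
The reference distribution is $t$ on the Barnard–Rubin adjusted degrees of
freedom (the small-sample formula combining $(m-1)/\lambda^2$ with the
observed-data df); complete-case and completed-data intervals use $t$ on
the residual df. These df conventions are genuinely open choices — several
defensible alternatives exist — so they are recorded in the run-metadata
sidecar that `write_run()` emits.

### Numerical and degenerate-input choices

* **Aliasing.** Design columns that are constant or collinear (the
  indicator when nothing is missing; $U$ terms among complete rows when
  $R_A = 1 - U$; $M$ vs $U$ in the U-observed deterministic case) are
  dropped by pivoted QR and recorded on the fit, rather than failing the
  replicate. This preserves the factorial balance of the grid. Column order
  puts the exposure term before the indicator and $U$ terms, so the
  coefficient of interest survives whenever the design has any rank.
* **Degenerate replicates.** A replicate with zero observed (or zero
  missing) exposures is flagged and its affected fits are recorded as
  failures; it is *not* regenerated, since conditioning on non-degeneracy
  would bias the missingness proportion. Summaries are computed over
  successful replicates with an explicit failure-count column.
* **$m = 1$ pooling boundary.** $B$ is undefined; we return $T = W$ with
  the residual df and flag the row.
* **Percentiles.** Linear interpolation between order statistics (R's
  default type 7), recorded in the metadata sidecar.
* **Seeding.** A single study seed deterministically yields a seed per
  (cell, replicate, stream) via iterated Lehmer-style mixing modulo
  $2^{31}-1$, with separate streams for data generation and for each
  imputation variant. Any execution order, parallel partition, or choice to
  run only one analysis variant reproduces identical numbers.

## The factorial grid

`grid_spec()` defaults encode the full study design: $\alpha_U, \beta_A,
\gamma_U \in \{0, 0.1, 0.5, 1\}$, $\beta_U \in \{-1, 0, 0.1, 0.5, 1\}$,
$\beta_{UA}, \gamma_{UA} \in \{0, 0.5\}$, $\sigma_Y \in \{0.1, 0.5, 1\}$,
marginal missingness $\in \{0.25, 0.5, 0.75\}$, with $\gamma_A = 1$,
$\sigma_A = 1$, $\pi_U = 0.5$ and $n = 10{,}000$ fixed — 11,520 cells — plus
the deterministic stratum with $\pi_U \in \{0.25, 0.5, 0.75\}$ and no
$\beta$s, 288 cells, for 11,808 in all. Whether $U$ is available to the
analyst is an analysis-level variant, not a grid factor, so both variants
can be run on the same generated data.

Per cell and replicate the engine retains, for each method and coefficient,
the 2.5th/25th/50th/75th/97.5th percentiles, the mean (both are reported
since figures could reasonably display either), the empirical SE, the mean
model-based SE, the mean CI length, and coverage. The default coverage
target for the exposure coefficient is 1 (the fixed conditional effect);
`run_grid(use_delta_target = TRUE)` switches to the standardized marginal
effect $\delta_A = \gamma_A + \pi_U \gamma_{UA}$ from `true_effects()`.

## Analytic oracles

Two closed forms anchor the simulations. First, standardization:
$\delta_A = \gamma_A + \pi_U\,\gamma_{UA}$, with conditional effects
$\gamma_A$ and $\gamma_A + \gamma_{UA}$; at $\gamma_A = 1$,
$\gamma_{UA} = 0.5$, $\pi_U = 0.5$ these are $1.25$, $1$ and $1.5$. Second,
in the deterministic case $R_A = 1 - U$ with no interaction, the indicator
coefficient of MI(R+A) targets $\gamma_U$ but is attenuated by regression
dilution — the imputed exposure is a noisy surrogate among exactly the rows
where the indicator is 1 — to approximately
$$ \gamma_U\,\frac{\sigma_Y^2}{\gamma_A^2 \sigma_A^2 + \sigma_Y^2}, $$
while the exposure coefficient itself remains unbiased for $\gamma_A$.
`dilution_attenuation()` embodies the formula; the package treats it as a
testable prediction against the simulation rather than re-deriving it
symbolically, because the artifact's job is numerical verification. Its
error order in $n$ is not characterised, so tests compare it with
Monte-Carlo bands, not exact equality.

```{r analytic}
true_effects(gamma_A = 1, gamma_UA = 0.5, pi_U = 0.5)
dilution_attenuation(gamma_U = 1, gamma_A = 1, sigma_A = 1, sigma_Y = 1)
```

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: one incomplete
continuous exposure, a single binary confounder, Gaussian exposure and
outcome, logistic or deterministic missingness, $n = 10{,}000$ per
replicate and 200 replicates per cell as defaults. Real routinely collected
data differ in ways deliberately out of scope: multivariate missingness
patterns, non-normal or categorical exposures, multiple (or continuous)
unmeasured confounders, and measurement error. Passing tests therefore
certify the behaviour of the estimators *under the stated structural
models*, not robustness beyond them; the deterministic $R_A = 1 - U$ case
in particular is an idealisation of "a test is run only when an unrecorded
condition is met".

## Problem sizes used by the test-suite

The full 11,808-cell × 200-replicate grid is a cluster-scale computation
and is not run by the tests. The suite instead verifies the headline claims
on their exact cells at full study size (200 replicates of $n = 10{,}000$),
runs a 20-cell stratified subsample of the grid at 50 replicates
end-to-end, and uses million-row single datasets as large-sample oracles
where a long-run regression is the reference. Small-$n$ configurations
(a few hundred rows) are used only for structural properties — masking,
aliasing, seeding, serialization — where sample size is irrelevant.

## Worked example

```{r example, eval = FALSE}
library(mimisim)

# the extreme proxy case: A observed exactly when U = 0
cfg <- scenario_config(missingness = "deterministic", pi_U = 0.5,
                       gamma_U = 1)
res <- run_cell(cfg, replicates = 50, study_seed = 42)
subset(res$summary, coefficient %in% c("A", "M"),
       select = c(method, coefficient, mean, emp_se, coverage))
```

Standard MI overestimates the exposure effect here (it treats an MNAR
mechanism as MAR), the indicator variants recover it, and the MI(R+A)
indicator coefficient sits near the diluted value 0.5 rather than
$\gamma_U = 1$ — the three behaviours the analytic section predicts.

## Known limitations

* Model-based SEs are classical OLS SEs; no sandwich or bootstrap variants.
* Exactly one incomplete variable; no chained-equations machinery.
* Bias formulas are provided only for the deterministic no-interaction
  case; other cells are characterised empirically.
* The scenario classifier's treatment of patterns absent from the six DAG
  panels is a labelling convention, as described above.
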