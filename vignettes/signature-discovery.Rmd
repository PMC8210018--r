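---
title: "Prognostic signature discovery by bootstrap LASSO Cox regression"
author: "prognosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic signature discovery by bootstrap LASSO Cox regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognosig)
```

## The problem

Given a cohort of patients with genome-wide expression values (TPM/FPKM
scale, genes or splicing isoforms) and right-censored follow-up, we want a
small *signature* — a set of features with signed weights — whose linear
combination predicts survival, and we want to quantify that prediction with
standard survival statistics. Fitting a single Cox model to thousands of
features is hopeless; fitting a single penalized model is unstable, because
the particular features a LASSO keeps depend strongly on the sample. The
approach taken here resamples the *feature space*: many small random groups
of features are fitted independently, each with its own cross-validated
LASSO Cox model, and each feature's evidence is aggregated across all the
groups that contained it.

## The model

Each bootstrap iteration draws $G$ features uniformly without replacement
out of the $N$ available and fits an L1-penalized Cox proportional-hazards
model to that group,

$$\hat\beta = \arg\max_\beta \; \ell(\beta) - \lambda \sum_j |\beta_j|,$$

where $\ell$ is the Cox partial log-likelihood. The penalty weight
$\lambda$ is chosen per iteration by 10-fold cross-validated partial
likelihood over a 50-point geometric grid spanning
$[\lambda_{\max}\cdot 10^{-3}, \lambda_{\max}]$, with folds stratified by
event status so that sparse events spread evenly. Predictors are
standardized internally before penalization (the L1 penalty is
scale-sensitive and expression features vary over decades); coefficients
are reported back on the input scale.

After $B$ iterations, a feature sampled in $k$ iterations has $k$ fitted
coefficients, many of them exactly zero. Its signature coefficient is the
**mean over all iterations that sampled it, zeros included**. Zeros-in
averaging is deliberate: a feature that the LASSO keeps only occasionally
is shrunk toward zero in proportion to its instability, which is exactly
the ordering one wants when ranking candidates. The signature records, per
feature, the aggregated coefficient, `times_sampled` ($k$) and
`times_nonzero`.

### Sampling-frequency law

Because each iteration places exactly $G$ of $N$ features, a feature's
selection count is Binomial($B$, $G/N$) and its expected value is

$$f = \frac{BG}{N}.$$

When the iteration count is not supplied it defaults to
$B = \lceil (N/G)^2 \rceil$, which makes $f = N/G$ — large enough that
every feature is assessed tens of times at typical $N/G$, while keeping
the run linear in $B$. The test suite verifies the law directly
(mean count and a chi-square goodness-of-fit against the binomial at
$N = 500$, $G = 10$, $B = 2500$).

### Risk score and survival validation

A fitted signature scores any sample as
$\mathrm{score}_s = \sum_f C_f \, E_{s,f}$ — coefficients times expression
values. The survival stage checks the proportional-hazards assumption of
the score (Schoenfeld residual test; a violation warns prominently but
does not stop the analysis, because the score is the object under test),
splits the cohort at the median score (samples at or below the cutoff are
"low"), and summarizes the contrast with a log-rank test, per-group
Kaplan-Meier curves with median survival, and a Cox hazard ratio. The HR
is reported for the low group against the high reference, so a protective
low score gives HR < 1. An ROC/Youden cutoff is available as an
alternative to the median: sensitivity and specificity for classifying
event status are computed over candidate thresholds and Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$ is maximized. By default the ROC
is kernel-smoothed (Gaussian kernel, bandwidth
$\mathrm{sd}(\mathrm{score}) \cdot n^{-1/5}$); an exact empirical mode
exists and is what the brute-force oracle test checks against, since the
smoothed optimum can sit between observed scores.

## Preflight filters

Four gatekeeping steps decide what enters the regression:

* **Cohort viability** — fewer than 10 samples is a hard reject (the
  10-fold cross-validation inside every iteration needs them); fewer than
  20 features drops to a single penalized regression instead of the
  bootstrap.
* **Endpoint variability** — cohorts with fewer than 2 events or fewer
  than 2 censored samples are rejected; partial likelihoods degenerate
  without contrast in the endpoint.
* **Variance filter** — features with sample variance strictly below the
  cutoff (default 0.01 on the analysis scale) are removed; a feature
  exactly at the cutoff stays.
* **Schoenfeld screen** — each feature is tested univariately for
  proportional hazards (correlation of scaled Schoenfeld residuals with
  Kaplan-Meier-transformed time, the transform being configurable);
  features with p below 0.05 (configurable) are removed, as are features
  whose univariate Cox fit fails numerically — a thousand-feature screen
  must not crash on a degenerate column.

Inside the bootstrap, every drawn group is vetted for collinearity: a pair
is flagged when its absolute Spearman correlation exceeds 0.8 with
p < 0.05 (asymptotic t approximation), and when more than a fraction
$P$ (default 0.3) of the group's pairs are flagged, the whole group is
redrawn, up to 100 times. Redrawing the group, rather than swapping single
members, keeps the marginal inclusion probability uniform.

## Clinical covariates

The multivariate stage screens each clinical covariate in its own
univariate Cox model (categoricals dummy-coded against their most frequent
level, which keeps the reference stable across resamples) and keeps those
with Wald p below 0.2 by default; the score always enters the final model.
The final fit reports per-term hazard ratios with 95% CIs, forest-plot
ready.

The *patient-oriented bootstrap* measures how stable each covariate's
association is: each of 100 cycles resamples patients with replacement,
re-checks covariate eligibility (a categorical needs a minority-category
frequency of at least 20% in the cycle), requires at least two eligible
covariables, and requires that removing rows with missing values in the
tested covariables leaves at least 70% of the cycle's data. A covariate is
"relevant" in a cycle when its Wald p (on the covariate's whole
coefficient block, df = levels − 1) is below 0.05; its relevance frequency
is relevant cycles over eligible cycles, and covariates at or above 25%
make the plotted list. Note one subtlety: the 70% rule is applied to rows
surviving null-removal, not to distinct patient identifiers — a
with-replacement resample contains only about 63% distinct patients in
expectation, so a distinct-identifier rule would void every cycle by
construction.

## The synthetic cohort generator

`generate_cohort()` produces the ground-truth data every statistical test
in the package runs on. Feature values are log-normal
($\exp(2 + 0.5 z)$, $z$ standard normal), giving the right-skewed,
strictly positive profile of TPM-scale expression. Survival follows a
Weibull proportional-hazards model: with linear predictor
$\eta = \sum_f \beta_f z_f$ on the *standardized latent* features,

$$T = \mathrm{scale} \cdot \left(\frac{-\log U}{e^{\eta}}\right)^{1/\mathrm{shape}},$$

with shape 1.2 and scale 800 days by default — median overall survival in
the several-hundred-day range typical of aggressive solid-tumor cohorts.
Censoring is administrative-uniform, with the upper bound calibrated by
root-finding so the realized censoring fraction hits the target.
Collinear blocks share a latent factor whose Pearson correlation
$r = 2\sin(\pi\rho_s/6)$ is chosen to hit a target *Spearman* correlation
$\rho_s$; low-variance features are near-constant columns.
`generate_clinical()` adds balanced and imbalanced categoricals, a numeric
age, an optional confounder with chosen correlation to the true linear
predictor, and missing-completely-at-random cells.

What the generator does *not* emulate: count noise and library-size
effects of real RNA-seq, gene-gene correlation beyond the planted blocks,
informative censoring, and batch structure. Tests passing on these
cohorts demonstrate the statistical machinery, not robustness to every
artifact of real data.

### A caution on marginal effects

Because the hazard is proportional in the *latent log-scale* features,
two things happen that users of the pipeline should expect on real data
too. First, Cox regression on raw expression is misspecified (the hazard
is log-linear in $\log E$, not in $E$); the `log2` flag exists for exactly
this reason and the package's own simulation studies use it. Second, even
on the log scale, a univariate model for one of several independent true
drivers omits the rest, and omitting covariates in Cox models attenuates
the marginal coefficient and induces a genuinely time-decaying marginal
effect (non-collapsibility: survivors at late times are depleted of
high-hazard patients on the omitted drivers). The univariate Schoenfeld
screen therefore removes a *true* driver noticeably more often than its
nominal level — about 10% per planted feature at $n = 150$ with five
strong drivers in our simulations, against the 5% nominal rate it holds
under the null. This is a property of marginal PH screening on multi-driver
data, not of the implementation; it is the main reason recovery-style
experiments on such cohorts plateau below perfection, and it motivates
keeping the screen's $\alpha$ configurable.

## Problem sizes used by the checked experiments

The test suite and `scripts/acceptance.R` fix their own scales: the
sampling-law check at $N = 500$, $G = 10$, $B = 2500$; the L1-vs-L2
shrinkage contrast on one $n = 150$, 50-feature cohort; oracle equivalence
(hand-rolled Newton-Raphson Cox, product-limit, log-rank arithmetic,
Youden scan) on fixtures of at most 10 samples; parameter recovery on
$n = 150$, 200-feature cohorts with five planted effects
$|\beta| = 0.8$ and 30% censoring, plan $B = 400$, $G = 10$, with a 70/30
train/validation split and a 0.035 coefficient cutoff refining the
signature before validation (mirroring how a broad signature is manually
narrowed before survival testing); and null calibrations at 500-1000
simulations. These sizes keep every experiment reproducible on a laptop
while leaving the statistical assertions well-powered.

## Numerical choices and degenerate inputs

* Ties at the stratification cutoff go to "low" (score strictly greater
  than the cutoff is "high"); a deterministic rule is required and this one
  keeps the median split balanced up to ties.
* Signature entries are ordered by descending $|C|$ with lexicographic
  feature-id tie-breaks, so output order never depends on input order; the
  bootstrap samples feature *names* in sorted order for the same reason.
* Per-iteration RNG streams are derived from the master seed by a counter,
  so a run is bit-reproducible and iterations are independent of how many
  preceded them.
* Iterations whose Cox fit fails at every $\lambda$, or whose group cannot
  be drawn under the collinearity tolerance within 100 retries, are
  skipped with a warning; a run only fails if *every* iteration is
  skipped.
* A group without events makes the group HR non-estimable and is reported
  as such rather than as an infinite interval.
* Writing a signature prints coefficients with 17 significant digits, so
  write-then-read round-trips are exact.

## Known limitations

* The signature aggregation (zeros-in mean) is one of several defensible
  rules; medians or nonzero-only means reweight unstable features
  differently, and no aggregated coefficient has the interpretation of a
  joint-model log hazard ratio.
* The ROC/Youden cutoff treats *ever-event* status as the binary outcome;
  a fixed-horizon definition would need time-dependent ROC machinery.
* The covariable relevance frequency inherits any chance association
  present in the full dataset — every resample sees the same accident —
  so a null covariate occasionally exceeds the 25% plotting threshold.
  The frequency is a stability diagnostic, not an error-controlled test.
* No multiple-testing correction is applied in the univariate screens;
  they are gatekeepers, not inference.
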