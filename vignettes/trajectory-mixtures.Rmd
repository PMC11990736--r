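---
title: "Censored-normal trajectory mixtures: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored-normal trajectory mixtures: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmix)
```

## The problem

Longitudinal behavioral phenotypes — here, daily voluntary alcohol
consumption of adolescent mice in a two-bottle free-choice assay, in grams of
alcohol per kilogram of body weight per day — are often heterogeneous across
individuals in ways a single mean curve hides. Group-based trajectory
modeling assumes the cohort is a finite mixture of latent groups, each with
its own smooth mean trajectory, and asks three questions: how many groups are
there, what are their curves, and which subject belongs to which group.

## The model

Subject $i$ contributes measurements $y_{it}$ on days $t$. Conditional on
membership in group $j$, measurements are independent with latent mean

$$\mu_j(t) = \beta_{j0} + \beta_{j1} t + \beta_{j2} t^2 + \dots$$

(polynomial order 0–4 per group; the reference analysis uses quadratics).
Consumption cannot be negative and a measured zero means "at or below the
detection floor", so the outcome follows a censored normal (Tobit) model
with shared residual SD $\sigma$: interior values contribute the Gaussian
density, values at the floor contribute the mass
$\Phi((y_{\min}-\mu_j(t))/\sigma)$. The subject-level group log-likelihood is
$\ell_{ij} = \sum_t \log f(y_{it} \mid \mu_j(t), \sigma)$ and the mixture
log-likelihood is

$$L = \sum_i \log \sum_j \pi_j e^{\ell_{ij}},$$

with membership proportions $\pi_j$. Posterior membership probabilities
follow Bayes' rule, $\mathrm{BPP}_{ij} \propto \pi_j e^{\ell_{ij}}$, and
subjects are classified by posterior argmax (ties, which require exactly
equal posteriors, break toward the lower group index).

Free parameters: all coefficients, one shared $\sigma$ (the reference output
prints a single sigma row, so per-group variances are deliberately out of
scope), and $k-1$ proportions — $p = \sum_j (\text{order}_j+1) + 1 + (k-1)$,
i.e. 12 for the three-group quadratic model. That count is pinned down by the
exact BIC/AIC identities of the reference fit
(`information_criteria(-3444.35, 12, 1805, 35)` reproduces
−3489.34 / −3465.68 / −3456.35).

## Estimation

`fit_trajectories()` maximizes $L$ by EM:

- **E-step**: posterior weights $w_{ij}$ from the current parameters,
  computed on the log scale with log-sum-exp stabilization (likelihood gaps
  of hundreds of log units neither overflow nor underflow).
- **M-step**: $\pi_j = \bar w_{\cdot j}$ in closed form. Censoring removes
  the closed form for $(\beta, \sigma)$, so the weighted complete-data
  log-likelihood is maximized by warm-started BFGS with the analytic Tobit
  score, $\sigma$ on the log scale (clamped to $e^{\pm 20}$), and the
  coefficients rescaled by their basis-column magnitudes — the raw monomial
  basis $(1, t, t^2)$ spans four orders of magnitude on a 57-day axis and
  unscaled quasi-Newton steps diverge. The inner budget (default 30
  iterations) makes this a generalized EM step: started at the previous
  optimum it never decreases the objective, so the observed $L$ is
  non-decreasing across iterations (asserted on every fitted trace in the
  test suite).

**Initialization.** Mixture likelihoods are multimodal, so the fitter uses
multi-start EM: one start from a $k$-quantile split of the per-subject mean
levels plus `n_starts - 1` (default 19) random partitions. Each start runs a
short exploratory EM (`burn_iter = 6` iterations with a reduced inner
budget) to rank the starting basins cheaply; the best is then run to
convergence (relative $|\Delta L| < 10^{-8}$, at most 500 iterations, inner
tolerance $10^{-10}$). A fit that exhausts the budget is flagged
`converged = FALSE`, never silently returned.

**Reporting conventions.** Groups are relabeled by ascending intercept; for
the reference estimates this coincides with the published numbering
(1.39 < 1.61 < 2.48). Standard errors come from the inverse observed
information (numerical Hessian of $L$ at the optimum via `pracma::hessian`),
with proportions on a multinomial-logit scale and a delta-method
back-transform to percentages; p-values use the standard normal reference —
the reference output labels them t-tests without degrees of freedom, and the
asymptotic normal is the standard choice for ML Wald tests, so last-digit
differences from the published p-values are expected. A singular Hessian
(typical for overfitted candidates, e.g. $k = 4$ with a near-empty group)
yields `NA` SEs with a warning, which in turn fails the membership p-value
criterion below — not fabricated values.

## Choosing the number of groups

`scan_candidates()` fits each candidate $k$ (quadratic orders throughout, as
in the reference scan) and `select_most_parsimonious()` applies the
parsimony procedure, all thresholds strict and configurable:

1. every membership proportion > 10%, with every membership p-value < 0.1
   (the criteria apply to membership parameters only — the reference fit
   retains a trajectory coefficient with p = 0.1175, so coefficient p-values
   cannot be part of the rule);
2. every subject's maximum BPP > 0.95;
3. among candidates passing 1–2 (non-convergent fits excluded; $k = 1$
   always eligible as the baseline, its flags being not-applicable), the
   largest BIC with $N$ = observations wins.

Homogeneity ($k = 1$) is rejected when the winner's BIC exceeds the
single-group BIC by more than 10 — the conventional "very strong evidence"
cutoff on twice the log Bayes factor scale. A candidate failing **any**
criterion is excluded outright, reproducing the row logic of the reference
scan in which $k = 4$ dies on a membership percentage not significantly
different from zero. The observed separation in the selected model is
typically far sharper than criterion 2 requires (max BPPs above 0.999); that
is a description of the fitted cohort, not a second threshold.

## The synthetic cohort generator

No raw data accompany the reference analysis, so `generate_cohort()` is the
package's study stand-in and the generating truth of every simulation test:

- 35 subjects in latent groups of 4/26/5, using the published
  subject-to-group layout so descriptive outputs (e.g. the regimen
  cross-tab: late drinkers 2+2, early drinkers 3+2 across the 5%/10%
  regimens) line up with the reference study;
- the published quadratic coefficients, shared $\sigma = 1.60771$ and
  proportions as generating parameters; time is the raw study day (day 1 =
  first study day), under which the curves reproduce the published
  end-of-study magnitudes (early drinkers ≈ 6.4 g/kg/day at day 57);
- daily observations on days 6–57 — the days alcohol was available to every
  subject — with 15 cells missing at random. The reference analysis reports
  N = 1805 without stating the exact schedule; 35 × 52 − 15 = 1805 is a
  reconstruction (per-regimen availability days would give 1730), and both
  the schedule and the missing count are configurable. N = 1805 also implies
  the model consumed daily values, not 5-day averages; the 5-day averaging
  (`bin_average()`) is treated purely as a display and comparison
  convention.
- left-censoring at 0; the upper bound defaults to $+\infty$ (consumption
  has no physical ceiling) but is configurable for symmetry tests;
- a "5pct"/"10pct" regimen label on subjects 1–18 / 19–35, carried as
  metadata only — the model is fit across regimens, as in the reference
  analysis.

A homogeneous scenario (`homogeneous_model()`: every subject on the
non-drinker curve) supports null-calibration of the selection procedure; the
non-drinker curve is used because it describes the cohort majority.
`generate_covariate_channels()` adds body-weight/food/water-style channels
as group means plus Gaussian noise for comparison-pipeline tests (e.g. a
lower water-intake mean for early drinkers).

What the generator does **not** emulate: serial correlation beyond group
structure, regimen-dependent outcome regimes (the 2%-alcohol ramp days),
attrition, or measurement drift. Passing recovery tests therefore shows the
estimator is correct under the model's own assumptions, not that real
drinking data satisfy them.

## Group comparison

`summarize_groups()` reports per-(group, bin) mean ± SEM over subject-level
5-day bin means (SEM undefined for single-subject cells, reported `NA`).
`two_way_anova_tukey()` runs a group × time factorial ANOVA on the
subject-level bin means with Tukey HSD among groups within each bin
(studentized-range reference on the within-bin error; per-bin rather than
global comparisons, matching per-timepoint annotation of consumption
timelines). The reference analysis ran its ANOVA in a point-and-click
package without stating the repeated-measures treatment; the factorial on
subject-level bin means is a documented approximation, and directional
significance patterns — not exact p-values — are the contract.
`label_phases()` condenses each bin's Tukey pattern, ranking groups by bin
mean: "early" (lowest two groups indistinguishable, both below the top),
"transition" (all pairs distinct), "end" (top two indistinguishable, both
above the lowest), "other" otherwise.

## Problem sizes and numerical choices

The simulation studies in the test suite and the acceptance script use the
reference-scale cohort (35 subjects, 1805 observations) with 20 replicate
seeds for recovery, separation and selection checks, and 50 replicates for
the null calibration of the homogeneity test, scanning k = 1–3 under the
homogeneous truth (a multi-group candidate must pass every criterion for a
rejection, which is the mechanism the guard exercises) and k = 1–4 under the
three-group truth. These sizes give binomial standard errors of a few
percent on the monitored rates while keeping a full run in the minutes
range. Brute-force oracles (assignment-vector enumeration, direct
censored-regression optimization) run on 3–12-subject instances where
enumeration is exact.

Degenerate inputs are handled explicitly: a collapsing group's proportion is
floored at $10^{-10}$ inside EM so its coefficients stay estimable; value
vectors at the censoring floor are detected by `y <= lower` (the generator
records censored draws exactly at the bound); empty (group, bin) cells abort
the ANOVA with the offending cell named.

## Known limitations

- Standard errors and p-values follow the package's own ML conventions and
  are not guaranteed to match other trajectory software beyond estimate
  scale; the published example ratio (membership 11.43% / SE 5.394 → t ≈
  2.12) is reproduced to printed precision.
- Per-group residual variances, covariates on membership, and
  missing-not-at-random dropout are out of scope.
- BIC-based selection at n = 35 subjects is consistent but not powerful for
  subtle group structure; the null-calibration property (homogeneity
  rejected in ≤ 10% of homogeneous cohorts) is a guard the package tests,
  not a claim inherited from any external source.
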