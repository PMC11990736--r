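# trajmix

Group-based trajectory modeling of censored longitudinal consumption data.

## The problem

Longitudinal behavioral assays — the motivating case is daily voluntary
alcohol consumption of 35 adolescent outbred mice in a two-bottle
free-choice paradigm, measured in g alcohol / kg body weight / day over a
57-day window — show strong individual heterogeneity that a single mean
curve hides. `trajmix` is for researchers who want to resolve such a cohort
into latent **trajectory groups**, decide **how many** groups the data
support, and compare the phenotypes of the classified groups.

## The model

The cohort is a finite mixture: subject *i*, if it belongs to group *j*,
has measurements

y_it = β_j0 + β_j1·t + β_j2·t² + … + ε_it,  ε_it ~ N(0, σ²),

observed through left-censoring at 0 (a measured zero is "at or below the
floor" and contributes the probability mass Φ((0 − μ_j(t))/σ) — the
censored-normal / Tobit outcome model). The mixture log-likelihood

L = Σ_i log Σ_j π_j exp(ℓ_ij),  ℓ_ij = Σ_t log f(y_it | μ_j(t), σ),

is maximized by multi-start EM with a quasi-Newton M-step and a final
direct polish; subjects are classified by Bayesian posterior probability
(BPP), and the number of groups is chosen by a parsimony procedure: all
membership proportions > 10% with p < 0.1, every subject's max BPP > 0.95,
largest BIC (reported as L − (p/2)·ln N) among the candidates passing, and
homogeneity rejected only when the winner beats the single-group BIC by
more than 10.

No raw data accompany the reference analysis, so the package ships a
synthetic-cohort generator (`generate_cohort()`) whose defaults are the
published estimates — quadratic curves for "late drinkers" (n = 4),
"non-drinkers" (n = 26) and "early drinkers" (n = 5), shared σ = 1.60771,
days 6–57 with 15 missing cells (N = 1805 observations) — making every
stage testable end to end.

## Worked example

```r
library(trajmix)

cohort <- generate_cohort(study_design(seed = 11), generating_model())
nrow(cohort)
#> [1] 1805

fit <- fit_trajectories(cohort, trajectory_spec(k = 3, order = 2), seed = 11)
print(fit)
#> Censored-normal trajectory mixture: k = 3, orders 2/2/2
#>   subjects 35, observations 1805, free parameters 12
#>   logLik -3062.01 | BIC(N=obs) -3107.00 | BIC(N=subj) -3083.34 | AIC -3074.01
#>   membership %: 11.43, 74.29, 14.29 | sigma 1.5729 | converged: TRUE

table(fit$assignment)
#>  1  2  3
#>  4 26  5
```

The fit recovers the generating structure: membership percentages
11.43/74.29/14.29, classified sizes 4/26/5, σ̂ = 1.57 against the generating
1.61, and every subject classified with max BPP ≈ 1. `fit$estimates` holds
the full coefficient table (estimate, SE, t, p, with membership rows on the
percentage scale). The scan

```r
sel <- select_most_parsimonious(scan_candidates(cohort, k_values = 1:4, seed = 11))
sel$selected_k          # 3
sel$delta_bic_vs_k1     # ~691: homogeneity rejected (threshold 10)
```

reproduces the published decision logic, including the exclusion of the
k = 4 candidate on its membership criteria. Downstream,
`summarize_groups()`, `two_way_anova_tukey()`, `label_phases()` and
`regimen_crosstab()` compare the classified groups (5-day bins, group ×
time ANOVA with per-bin Tukey HSD, early/transition/end phase labels,
group-by-regimen counts).

The staged workflow lives under `analysis/`
(`01_simulate_cohort.R` → `04_compare_groups.R`, run from the repository
root; each writes its tables under `results/`), and `run_pipeline()` runs
everything in one call with full provenance (seed, config hash, run log).

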