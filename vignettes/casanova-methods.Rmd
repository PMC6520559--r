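---
title: "Clustering repeated qHTS concentration-response profiles with casanova"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering repeated qHTS concentration-response profiles with casanova}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casanova)
```

## The problem

Quantitative high-throughput screening (qHTS) tests thousands of compounds,
each at a series of concentrations (here, 15-point curves), and usually more
than once. The repeated curves for one compound -- its *repeats* -- are not
clean replicates: supplier, library preparation site, compound purity and
experimental day can all differ between them, and in practice the repeats of
a single compound often fall into visibly different response patterns.
Summarizing such a compound with one potency number (the AC50, the
concentration of half-maximal response) silently averages over disagreeing
experiments. `casanova` (Cluster Analysis by Subgroups using ANOVA)
automates the quality-control step: it groups each compound's repeats into
statistically supported clusters, classifies the compound, and reports AC50
per cluster rather than per compound.

## The clustering model

All responses are percent of the positive control, so the assay's
*noise band* is a symmetric detection limit `±m·σ` centered at zero, with
`σ` the standard deviation of responses at the lowest tested concentration,
pooled over every profile in the study, and `m = 3` by default. We pool
study-wide because detection limits are a property of the assay, not of a
compound; a per-compound option exists (`estimate_noise_band(per_compound =
TRUE)`), as does an external override for labs that prefer DMSO-control
plates as the reference (`sigma =`). Membership is closed-interval: a
response exactly at the limit is *within* the band, since only strict
exceedance counts as "extending beyond" it. Repeats lying entirely within
the band are set aside as the "noise" cluster.

For the remaining (active) repeats, the tested concentrations are binned by
rank into five consecutive bins (3 points each for 15-point curves; any
remainder goes one-per-bin starting at the lowest bin) to form a five-level
concentration factor CONC, and the compound-specific two-way fixed-effects
model

R_ijk = mu + CONC_i + REPEAT_j + gamma_ij + eps_ijk

is fitted, with observation-level error eps_ijk. The decision tree then runs
on the classical F tests at level `alpha` (default 0.05; "significant"
always means p strictly below `alpha`):

* interaction and REPEAT significant: repeats are ranked by overall mean
  response and split between ranked neighbors that differ significantly,
  then the per-bin subgroup analysis further refines the clusters;
* only the interaction significant: subgroup analysis alone;
* only REPEAT significant: the overall-mean split alone;
* neither: one cluster.

Neighbor comparisons use a pooled two-sample t statistic,
`t = (m2 - m1) / sqrt(MSE (1/k1 + 1/k2))` on the ANOVA error degrees of
freedom, where the `k` are the observation counts behind each mean. The
subgroup analysis repeats this per concentration bin, from the highest
concentration to the lowest, using cell means, and each pass only refines
the existing blocks -- clusters can split but never merge, so the final
partition always refines the overall-mean split, and lowering `alpha` can
only reduce the number of clusters.

Each active cluster is then tested for *conclusiveness*: the per-bin cluster
means lying beyond the detection limit (on the dominant side of exceedance)
are compared with that limit by a one-sided one-sample t-test at
`conclusive_alpha` (0.05). At least two exceeding bin means are required --
with one, the test has no degrees of freedom and the cluster is inconclusive
by convention. Compounds are classified into five classes: Case 2 (all
repeats within noise), Conclusive/Inconclusive Case 1 (one cluster holding
all repeats), and Conclusive/Inconclusive Case 3 (multiple clusters,
counting a non-empty noise cluster as a cluster; conclusive when at least
one active cluster is).

### Numerical and design choices

Several details are genuinely open in this design and were fixed once:

* **ANOVA on active repeats only.** Removing within-noise repeats before
  fitting is the only reading consistent with having a noise cluster at all;
  the alternative (fitting all repeats) would let pure-noise repeats inflate
  the MSE.
* **Sums of squares from cell means.** The rank-binned layouts are
  proportional-frequency designs, so the classical sequential sums of
  squares have a closed form; this is what the package computes, and the
  test suite verifies F and p against `anova(lm(...))` to 1e-8 relative on
  randomized instances. With up to ~200 repeats per compound this is orders
  of magnitude faster than building the `lm` design matrix per compound.
* **No multiplicity adjustment in neighbor tests.** The threshold is swept
  as a raw per-comparison level; users calibrate `alpha` against the
  Type A/B trade-off instead.
* **Ties.** Ranking ties break by repeat identifier; cluster labels are
  assigned in order of decreasing mean response. Results are invariant to
  relabeling repeats.
* **Saturated designs.** With one observation per cell the interaction is
  not estimable; the additive model is fitted and the interaction branch of
  the decision tree is skipped.
* **Degenerate variance.** An exactly zero MSE is refused as degenerate
  data; a zero MSE reaching a neighbor test (possible when supplied
  externally) cuts every unequal pair.

## Potency estimation

Per-profile AC50s come from a three-parameter Hill fit,
`E(R) = RMAX / (1 + 10^(-h (log10 C - log10 AC50)))`, by bounded nonlinear
least squares (`stats::nlminb` with analytic gradients) in the
(RMAX, h, log10 AC50) parameterization. Five deterministic starts place the
initial log10 AC50 at the 10/30/50/70/90% quantiles of the tested log10
concentrations and the best final residual sum of squares wins. Bounds --
log10 AC50 within the tested range widened by 2 decades, RMAX within twice
the largest absolute response, h in [0.01, 10] -- keep plateau-truncated
curves identifiable; they matter most for the truncated-plateau bias results
below and are exposed to the user. Standard errors come from the asymptotic
covariance `s^2 (J'J)^{-1}`; a fit whose covariance is singular is flagged
non-converged. One round of outlier removal (absolute studentized residual
above 3, at most 20% of points, never below 5 remaining points) precedes a
refit; this concrete rule stands in for procedures that real pipelines
inherit from their fitting libraries.

Cluster-level AC50 aggregates the per-profile estimates on the log10 scale
by one of four strategies: arithmetic mean, median, inverse-variance
weighted mean with weights (1/SE)^2, or a single pooled fit to all points of
the cluster. Potency is reported per cluster, never averaged across the
clusters of a Case 3 compound. A zero SE under weighting receives the
largest finite weight present rather than an infinite one.

## What the simulator emulates

`simulate_study()` generates studies shaped like Tox21 Phase II screens:
15 concentrations log-spaced from 1e-4 to 100 uM; per compound, 1-4 clusters
and per cluster 3-54 repeats drawn from configurable probability vectors;
per cluster, a curve model (Hill or bell-shaped gain-loss with shared slope
and zero bottom asymptotes, 50/50 by default), a mean log10 AC50 drawn
without replacement from a decade grid (tenfold spacing: 1e-4..100 uM;
hundredfold: 1e-4, 1e-2, 1, 100), a realized log10 AC50 ~ Normal(mean, 1/6)
so that essentially all clusters stay at least a grid step apart, a mean
maximal response mu_RMAX ~ Uniform(3σ, ResponseRange), RMAX ~
Normal(mu_RMAX, sqrt(MSE)) and slope h = |Normal(1, sd 3)|. A gain-loss
cluster draws its loss-phase AC50 from the grid values at least one
(tenfold) or two (hundredfold) steps above its gain mean, falling back to
1000 uM when none qualifies. All repeats of a cluster share its parameters;
points get heteroscedastic noise Normal(0, sd = |E(R)|·CV), so a zero
expected response carries no noise. Compounds are emitted only if at least
one response falls outside the ±3σ band, mirroring how real screens only
analyze detectable compounds.

The noise presets (low / moderate-low / moderate-high / high, MSE = 4 /
6.25 / 9 / 16 on a 100-unit response range, band σ = sqrt(MSE)) are
package-chosen constants spanning the plausible range for normalized
reporter assays: residual standard deviations of 2-4% of the positive
control and detection limits of ±6 to ±12%. They are deliberately
configuration, not estimates of any particular assay. The per-repeat
variation of real screens that the generator does **not** emulate includes
supplier-linked systematic shifts within a true cluster, plate-position
artifacts and concentration-grid differences between repeats; passing the
simulation benchmarks therefore demonstrates correctness of the method
under its own model, not performance on any specific real assay.

When clustering simulated studies, the known generator σ is supplied to the
noise band (the same external-σ override offered for real DMSO-based
limits) instead of re-estimating it, because for low-AC50 compounds the
lowest-concentration responses contain signal, which would inflate a pooled
estimate.

`simulate_estimation_study()` generates the separate single-cluster design
used for estimator evaluation: n in {3, 6, 9, 12} identical-truth Hill
profiles per compound with slope 1, true AC50 at 0.001 uM (upper plateau
only within the tested range), 0.1 uM (both plateaus) or 10 uM (lower
plateau only), RMAX in {25, 50, 100} and homoscedastic Normal(0, 5%) or
(0, 10%) noise.

## Evaluation

Against simulation truth, a compound scores a **Type A** error when a true
single-cluster compound is classified Conclusive Case 3 (over-splitting),
and a **Type B** error when a true multiple-cluster compound is classified
Conclusive Case 1 (over-merging). Rates divide by all compounds by default
(`conditional = TRUE` divides by the truth-type counts).
`threshold_sweep()` recomputes both rates across a grid of p-value
thresholds; Type A is nondecreasing and Type B nonincreasing in the
threshold, with the endpoints behaving exactly: at `alpha = 0` active
repeats always form one cluster, at `alpha = 1` every distinct-mean
neighbor pair splits. `bias_variance_table()` summarizes per-compound AC50
estimates as bias = mean(estimate - truth) and the sample variance of the
estimates, per (true AC50, RMAX, n, method) cell.

## Problem sizes used by the shipped checks

The package's own benchmark runs (the acceptance script and the slow test
file) use 10 studies of 500 compounds for the clustering error rates and
2000 compounds per cell for the estimator study; at these sizes the
Monte-Carlo standard error of an error rate is about 0.2-0.3 percentage
points and that of a bias about 0.002-0.003 log10 units, comfortably below
the margins being checked. Both error rates at alpha 0.05 sit well below
the 5% benchmark, and the weighted-average estimator in the both-plateau
cells shows |bias| under 0.01 and variance under 0.04. In the
truncated-plateau cells the simple-average bias of this package's bounded
fits is smaller than what unbounded fitting pipelines typically report;
the direction and ordering of the effects (simple averaging worst, weighted
averaging most repeatable) are reproduced.

## Known limitations

* The ANOVA assumes homoscedastic errors within a compound, while both
  real assays and the simulator are heteroscedastic in the response level;
  the F tests are therefore approximate, which is one reason the conclusive
  t-test and the class definitions -- not raw F significance -- carry the
  final interpretation.
* Metadata (supplier/site/purity/day) is carried through but not used to
  explain clusters; association testing is out of scope.
* Plate-level normalization and row/column/plate correction are assumed
  done upstream; inputs are normalized percent-of-control responses.
* The gain-loss model is used for data generation; fitting uses the Hill
  model only, as potency reporting in this workflow is gain-side.

## A worked example

```{r example, eval = FALSE}
library(casanova)

sim <- simulate_study(sim_design(n_compounds = 200), sim_noise("moderate"),
                      seed = 1)
asg <- casanova_study(sim$study)
table(vapply(asg, function(a) a$case_class, character(1)))

pot <- estimate_potency(sim$study, asg, method = "weighted")
score_errors(sim$truth, asg, 0.05)
```
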