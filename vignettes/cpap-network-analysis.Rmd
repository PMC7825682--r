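---
title: "Patient compatibility networks and the neck-circumference indicator of CPAP response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient compatibility networks and the neck-circumference indicator of CPAP response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpapnet)
```

## The problem

Obstructive sleep apnea (OSA) is graded by the apnea–hypopnea index (AHI,
events per hour of sleep): normal below 5, mild from 5 to below 15, moderate
from 15 to below 30, severe at 30 and above. Continuous positive airway
pressure (CPAP) is the standard therapy, and a one-night titration gives an
early readout of treatment response as the drop in AHI. The question this
package operationalizes is whether simple anthropometric measurements —
above all neck circumference (NC) — indicate who will respond well, and what
NC cutoff best separates responders, using a network-medicine analysis
rather than a single regression.

The pipeline has two stages. The first builds a *risk-compatibility
network* over a CPAP-titration cohort, detects phenotype communities by
modularity maximization, and labels each community by its AHI improvement.
The second stage evaluates NC as a screening score on a larger
OSA-vs-control cohort pair (ROC/AUC, Youden-optimal cutoff, likelihood
ratios) and then carries the resulting cutoff back to the network's response
classes.

## The compatibility network

Each patient is discretized into six parameter classes
(`discretize_patients()`):

* gender (M/F);
* age group: (−∞,20], (20,40], (40,60], (60,∞) years — the source grading
  prints overlapping boundaries ("≤20", "20–40", …), so the package fixes
  half-open intervals closed on the right and exposes the breaks in
  `discretization_rules()`;
* hypertension: systolic > 140 or diastolic > 90 mmHg (strict), or an
  explicit flag for cohorts recorded only as hypertensive yes/no;
* obesity: BMI > 30 kg/m² (strict);
* thick neck: NC ≥ 43 cm for men, ≥ 40 cm for women (thin neck is the
  complement);
* sleepiness: Epworth score ≥ 11.

Two patients are *risk-compatible* when they fall in the same class for at
least 4 of the 6 parameters; the shared-class count (4–6) is kept as the
edge weight (`build_network()`, default threshold 4). All six parameters
weigh equally. The threshold is the decisive resolution dial:
`threshold_sweep()` shows that at 1 the graph is a single dense community
while at 6 it shatters into many small components; 4 is the balanced
default. Isolated patients stay in the network and become singleton
communities.

## Community detection

Modularity of a partition $\{C_1,\dots,C_m\}$ is

$$M = \sum_{C} \left[ \frac{w_{in}(C)}{W} - \left(\frac{S_C}{2W}\right)^2 \right],$$

with $W$ the total edge weight, $w_{in}(C)$ the intra-community weight and
$S_C$ the accumulated node strength (degrees when unweighted).
`detect_communities()` maximizes it with the greedy local-move +
aggregation scheme (Louvain): nodes are visited in a deterministic order
derived from the seed, ties in the gain go to the smallest community id,
and a handful of seeded restarts keeps the best partition, so results are
reproducible and invariant to node relabeling. Weight-aware modularity is
the default (weights 4–6 carry information about how compatible two
patients are); the unweighted variant is a flag. No resolution parameter is
exposed: the community count is an outcome, not a constraint.

`exhaustive_modularity_oracle()` enumerates every set partition of graphs
with at most 10 nodes and returns the global optimum; the test suite uses
it to bound the greedy optimizer's gap (≤ 0.02 over random small graphs)
and to pin exact values (two disjoint triangles: optimum exactly 0.5; a
single cluster: exactly 0 on any graph).

`force_layout()` provides the visual counterpart: an energy-based layout
with attraction exponent $a \ge 0$ on adjacent pairs and repulsion exponent
$r \in [-1, 0]$ on all pairs, minimizing
$\sum_{edges} d^{a+1}/(a+1) - \sum_{pairs} d^{r+1}/(r+1)$ (logarithmic
repulsion at $r = -1$). The defaults $a = 1, r = -1$ lie in the regime
where layout clusters and modularity communities coincide. Integration uses
backtracking on the energy, so the reported energy trace never increases;
`layout_community_agreement()` quantifies the coincidence as the ratio of
mean intra- to inter-community distances (< 1 means agreement). The layout
is a diagnostic, not part of the statistics.

## Treatment response

`severity_transition_table()` cross-tabulates severity classes before and
after CPAP per community. The response measure
(`ahi_improvement()`) is the percentage of patients severe before CPAP who
are normal or mild after; an alternative mode reports the relative drop of
the severe fraction. Communities at or above 85% improvement are labeled
the *best* response class, the rest *good*
(`label_response_classes()`); 85 sits between the ~87–89% and ~68–77%
ranges the two classes show, and is configurable.
`parameter_community_map()` reports, per community and parameter, the
majority class and whether it is *representative* (prevalence ≥ 0.70 by
default, boundary included — the 0.70 default sits in the gap between
observed non-representative (≤ 59%) and representative (≥ 84%)
prevalences).

`evaluate_nc_threshold()` closes the loop: predicted *good* if NC ≤ cutoff,
predicted *best* otherwise, scored against the community-derived labels in
both orientations. The two orientations are complementary classifiers on
one 2×2 table, so good-TPR ≡ best-TNR exactly, and all rates recompute
exactly from the stored per-community counts.

## Diagnostic statistics

`roc_auc()` computes the ROC curve with the test-positive rule
score > cutoff and the AUC from mid-ranks, so tied scores contribute ½ and
the identity AUC = U/(n₁n₂) with the Mann–Whitney U statistic holds to
machine precision (a property test asserts 1e−12). The confidence interval
is Hanley–McNeil (`auc_confidence_interval()`); DeLong is deliberately not
implemented — the interval mirrors the classical SPSS-style output this
kind of analysis reports. `youden_optimal_cutoff()` maximizes
J = sensitivity + specificity − 1 over candidate cutoffs (integer cm by
default), ties to the smaller cutoff. `cutoff_metrics_table()` adds PPV,
NPV and the likelihood ratios LR+ = se/(1−sp), LR− = (1−se)/sp.
Spearman and Mann–Whitney wrap the standard `stats` tests (average ranks,
t respectively normal approximations, two-sided p, 0.05 significance).

## The synthetic cohort generator

Real patient-level data for the three study groups are not redistributable,
so `generate_screening_cohorts()`, `generate_d1_like()` and
`generate_clustered_cohort()` emulate their statistical structure; the
defaults are the published cohort summaries:

* D1-like (CPAP titration): n = 145, 77.24% male, age 52.79 ± 12.32, BMI
  33.17 ± 6.64, NC 43.12 ± 5.06, Epworth 11.81 ± 4.98, AHI before
  52.28 ± 23.58 with 97.93% severe;
* D2-like (OSA-diagnosed males): n = 836, NC 44.91 ± 4.45, AHI
  41.68 ± 24.07, 93.06% severe, NC–AHI Spearman ρ = 0.35;
* D3-like (non-OSA male controls): n = 65, NC 40.67 ± 5.77, AHI
  6.01 ± 2.42.

Design choices, made once:

* All physiological quantities are normals truncated at zero, sampled by
  inverse CDF; the Epworth score is additionally rounded and clipped to
  [0, 24]. For variables with mean/SD ≳ 3 (NC, BMI) the truncated mean
  matches the nominal parameter to well within sampling error; for
  low-ratio variables (control-group AHI, Epworth) truncation shifts the
  realized mean upward — accepted, since those marginals play no role in
  the endpoints.
* A published mean/SD cannot coexist with a 97.93% severe fraction under a
  normal AHI; the generator therefore draws the severity stratum first and
  then the AHI from the corresponding band ([0,30) or [30,∞)) of the
  truncated normal, preserving both printed facts at the cost of an
  inflated realized mean.
* NC–AHI rank dependence comes from a Gaussian copula; the Spearman target
  maps analytically to the copula correlation, r = 2 sin(πρ/6), and
  survives the monotone marginal transforms, so the generated ρ is
  calibrated (±0.08 at n = 836 is the Fisher-z sampling band).
* The one-night response model: severe patients become normal/mild with
  probability 0.88 if thick-necked and 0.72 otherwise (midpoints of the
  87–89% and 68–77% class ranges); improvers land uniformly in [0, 15),
  non-improvers in [15, max(AHI, 35)]. Hypertension prevalence in the
  CPAP cohort is not published as a total; the default 0.68 is the
  community-size-weighted average of the per-community percentages.
* `generate_clustered_cohort()` plants communities by copying archetype
  profiles and flipping each class independently (age group resampled)
  with a given probability — a planted-partition benchmark for community
  recovery with known ground truth.

What passing tests on these cohorts do **not** show: the generator
reproduces marginals, one rank correlation and a two-class response
mechanism, not the joint distribution of a real clinic population. In
particular the D1-like cohort has *no* planted community structure beyond
what the marginals induce, so community counts on synthetic data are an
outcome of the threshold and the noise, and are not promised to equal four.

## Numerical and degenerate-input conventions

Modularity of an empty graph is defined as 0 with a warning. The greedy
move accepts gains above 1e−12 only, so floating-point noise cannot cycle.
Layout distances carry an ε = 1e−9 floor to avoid singular repulsion at
coincident points; a persistent failure to find a descending step raises an
error. The improvement percentage is undefined (error) when no patient is
severe before CPAP, as is the layout agreement ratio for a single
community and Spearman's ρ for constant input. Boundary conventions:
improvement ≥ threshold labels *best*; prevalence ≥ threshold is
representative; NC equal to the cutoff predicts *good* (cutoff included in
the lower group).

## Problem sizes used by the checks

The shipped tests run the screening AUC reproduction at the published
cohort sizes (836/65) over 50 seeds; the response-recovery check uses 600
simulated titration patients per seed over 20 seeds, a size at which the
binomial uncertainty of the thick-neck improvement (~0.02 SD) cleanly
separates the 0.9/0.7 response probabilities from the 85% labeling
threshold; oracle comparisons use graphs of 5–8 nodes, where exhaustive
enumeration is cheap.

## Known limitations

* Two of the four published community archetypes differ in a single
  parameter class (sleepiness). A planted-partition cohort built from those
  archetypes is therefore *not* modular at the "4 of 6" threshold — the
  two thick-neck male blocks connect almost as densely between as within
  and every modularity maximizer (ours and the igraph reference alike)
  merges them. Recovery benchmarks that expect all four communities back
  need archetypes pairwise differing in at least three classes; with the
  observed profiles the recoverable structure is three blocks.
* The published contingency table for NC thresholds contains internal
  inconsistencies (its 42-cm row counts 26 patients in one community of
  29; the prose attributes the 42-cm row's sensitivity/specificity to the
  41-cm threshold). The package reproduces the arithmetic of the
  consistent rows and makes no attempt to guess the intended figures.
* The Mann–Whitney p-value uses the normal approximation (with tie and
  continuity corrections); exact small-sample p-values are out of scope.
* One-night titration response only; no adherence or long-term outcome
  modeling, and no imputation — invalid records are rejected, not filled.
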