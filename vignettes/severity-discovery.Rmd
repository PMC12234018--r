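---
title: "Empirical severity-subgroup discovery for bulimia nervosa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical severity-subgroup discovery for bulimia nervosa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(severitree)
```

## The problem

The DSM-5 grades bulimia nervosa (BN) severity by the weekly frequency of
compensatory behaviors (mild 1–3, moderate 4–7, severe 8–13, extreme ≥ 14
episodes/week), but that banding was never empirically validated. Two
questions follow: is compensatory-behavior frequency even the right metric,
and if not, at what levels of the better metric do severity groups actually
separate? severitree implements a data-driven answer: recursive
partitioning of a cohort on candidate severity covariates
(shape/weight overvaluation and compensatory-behavior frequency), where
split quality is the fit improvement of a latent severity model refit in
the candidate child nodes (an SEM tree), plus a forest extension that ranks
the covariates, and a comparison stage that pits the discovered grouping
against three existing severity schemes.

## The latent severity model

Severity is modelled as a single latent factor $\eta$ with three manifest
indicators — z-scored cognitive eating-disorder symptoms (EDE-Q Global
computed *without* the two overvaluation items), depression, and anxiety —
sharing one loading $\lambda$:

$$x_k = m_k + \lambda\,\eta + \varepsilon_k,\qquad
\varepsilon_k \sim N(0, \mathrm{resid}_k),\quad k = 1,2,3 .$$

Identification fixes $\mathrm{Var}(\eta) = 1$, leaving 7 free parameters
($\lambda$, three manifest means, three residual variances) and implied
moments $\mu = (m_1, m_2, m_3)$,
$\Sigma = \lambda^2 J + \mathrm{diag}(\mathrm{resid})$ with $J$ the
all-ones matrix. With three indicators the model is just-identified up to
this constraint, so overall fit cannot be assessed — only *differences* in
fit between groups, which is exactly what the tree uses. An
unequal-loadings variant is deliberately out of scope (it is known to be
estimation-fragile with three indicators); the equal-loading constraint is
what makes the latent variable interpretable as a single severity axis.
The loading is reported on $\lambda \ge 0$ to resolve the sign
indeterminacy ($\lambda$ and $-\lambda$ imply the same likelihood).

Estimation is full-information maximum likelihood (FIML): each row
contributes the log-density of its *observed* indicator subvector under
the corresponding marginal of $(\mu, \Sigma)$, so the ~35% of records
missing anxiety cost no rows. Rows missing all three indicators are
rejected rather than silently dropped. Internally the likelihood and its
analytic gradient are computed in C++ from per-missingness-pattern
sufficient statistics (row counts, column sums, cross-products), which
makes an evaluation O(#patterns) instead of O(n); optimisation is
L-BFGS-B with residual variances on the log scale, fixed deterministic
starting values (λ = 0.5, sample means, half sample variances), a
convergence tolerance of ~1e-8 on the objective, and deterministic
restart jitter on nonconvergence.

## Preprocessing conventions

* **Overvaluation composite** = arithmetic mean of the two 0–6 items, so
  it lives on a 0.5-increment grid; missing if either item is missing (the
  composite is defined only as a two-item mean — no single-item fallback).
* **Compensatory frequency** = sum over vomiting, laxative/diuretic use and
  excessive exercise of the 28-day counts, each capped at 56 (two episodes
  per day) before summing; weekly frequency = 28-day total / 4.
* **EDE-Q Global without overvaluation** = mean of the retained cognitive
  items; missing below a configurable item-presence threshold (default
  50%).
* **Exclusions**, in order: all measures missing; Global < 0.5 while in
  residential/PHP care (an invalid-responding indicator at those levels of
  care); no core diagnostic BN indicators (a configurable item set —
  binge-eating and compensatory-behavior frequencies by default, since the
  authoritative item list is not public). Each rule is a pure predicate,
  so the retained set is order-invariant.
* **Standardisation** is within level-of-care stratum for all three
  indicators (sample SD, denominator n−1), because depression and anxiety
  are measured with different instruments across treatment settings.

## Fair split selection and the tree

At each node the candidate thresholds for a covariate are the midpoints
between consecutive distinct observed values (this is how cutpoints that
are not attainable composite scores, like 4.75 between grid values 4.5 and
5, arise). For count covariates with very many distinct values an evenly
spaced subset of at most `max_candidates` (default 24) midpoints is
scanned — a computational thinning, configurable.

The *fair* criterion controls for covariates' differing numbers of
response options: the node is randomly halved; every candidate of every
covariate is scored on half 1 by the likelihood-ratio improvement
$LR = 2(LL_\text{left} + LL_\text{right} - LL_\text{parent})$ (each fit a
full 7-parameter FIML refit); each covariate's best threshold is then
re-scored on half 2, and the covariate with the largest half-2 improvement
wins.

**The retention decision** uses the half-2 statistic, whose threshold was
chosen on the independent half 1, so it is a genuine pre-registered test —
asymptotically $\chi^2_7$ (both children re-estimate all 7 parameters).
Two calibration details matter in finite samples:

* children within each half must themselves satisfy `min_node_size`
  (default 30, on the order of the smallest severity group the method
  should resolve): a 7-parameter child model on a handful of rows makes
  the $\chi^2_7$ reference anticonservative, and the half-1 argmax
  preferentially proposes exactly such extreme thresholds;
* borderline decisions are verified against a parametric bootstrap of the
  confirmation statistic under the fitted parent model (59 replicates,
  preserving each row's missingness mask and split side; early exit as
  soon as retention is impossible; statistics with asymptotic
  p < 1e-6 skip the bootstrap, which cannot resolve p-values that small
  anyway). `tree_config(confirm = "chisq")` restores the purely
  asymptotic decision.

The deciding p-value is Bonferroni-corrected for the number of covariates
in play at the node (on by default). The full-node LR and p are then
*recomputed and reported* at the node — they are descriptive, like the LR
values printed at published tree nodes; deciding on them would re-use the
selection half and inflate the type-I error (in our null simulations, from
~5% to ~11%).

Conventions: left child is `covariate < threshold`; the threshold itself
routes right (so "≥ 5.75"-style group definitions read off directly).
Leaves are labelled 1..K in ascending threshold order. Rows missing a
node's chosen covariate contribute to that node's model fit but are not
routed further. Recursion stops at `min_node_size`, nonsignificance, or
`max_depth`. Given `tree_config(seed = )`, growth is fully deterministic
and `serialize_tree()` output is byte-identical across runs.

## The forest and covariate importance

`grow_forest()` grows trees on bootstrap resamples (size n, with
replacement, out-of-bag rows tracked), drawing `vars_per_split` covariates
uniformly at random as each node's candidate set; the reference analysis
design is 100 trees with one variable per split. Importance is **out-of-bag
permutation importance in −2 log-likelihood units**: for each tree, its
OOB rows are routed through the tree and scored by the leaf models' −2LL;
a covariate's contribution is the increase in that total when its values
are permuted before routing (one permutation per tree by default). The
table reports contributions summed across trees. A covariate never used at
any split of a tree leaves routing unchanged, so its contribution is
*exactly* zero — a useful integrity check. The per-split LL-gain ledger is
available from the tree nodes as a secondary diagnostic. The permutation
estimator is our operationalisation: published importance figures in this
area are reported in the same −2LL units but without a printed estimator
definition, so numeric importance values are comparable only within one
estimator.

## Competing severity schemes

* `assign_dsm5()`: weekly compensatory frequency banded by the half-open
  intervals [1,4), [4,8), [8,14), [14,∞) for mild/moderate/severe/extreme;
  below 1/week is flagged `subthreshold` rather than forced into mild.
  Whether published analyses banded averaged weekly frequencies or 28-day
  totals is not stated; the 28-day/4 convention is declared and
  configurable.
* `assign_clinical_overvaluation()`: clinical iff either item ≥ 4.
* `assign_purging_count()`: number of purging methods used (vomiting,
  laxatives, diuretics — excessive exercise is not purging): single vs
  multiple; patients purging by no method are excluded from this scheme's
  comparisons.
* `assign_semtree()`: leaf labels of a grown tree, or of the
  published-cutpoint reference tree (`reference_tree()`, thresholds
  1.25/3.75/4.75/5.75 shipped as a thresholds-only JSON fixture).

## Comparing schemes

For every scheme and every clinical characteristic *not used to define
that scheme* (compensatory frequency for DSM-5; overvaluation for the
tree, clinical-overvaluation and purging schemes — a configurable table),
`compare_schemes()` runs a one-way ANOVA and the planned contrasts, with
pairwise deletion per characteristic. Levene's test (center = mean;
median/Brown–Forsythe by flag) gates an automatic Welch correction
(Satterthwaite degrees of freedom); both classical and Welch statistics
are always returned. Effect size is partial eta squared
$SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$; two-group schemes
report $t^2/(t^2+df)$ so the variance summary is comparable across
schemes. Note the Welch-classical identity under equal variances and
sizes is exact only for two groups; with more groups the Welch denominator
correction differs from 1 even then.

Planned contrasts compare each lower severity group with the pool of all
higher groups: contrast $j$ gives group $j$ the coefficient $K-j$ and each
higher group $-1$ (for five groups the first contrast is proportional to
$+4,-1,-1,-1,-1$: group 1 versus groups 2–5). This is the orthogonal
family consistent with "lower versus higher" planned comparisons — the
superficially similar pool-versus-pool family (groups 1..j versus j+1..K)
is *not* pairwise orthogonal and is therefore not used. Coefficients are
orthogonal under equal weights and retained unchanged under unequal group
sizes (unweighted convention). Cohen's d divides the contrast estimate by
the pooled SD of the two contrasted pools of observations (not the omnibus
MSE). Groups left with fewer than two usable values after pairwise
deletion are dropped from that comparison.

`variance_summary()` reports min/max/mean variance explained per scheme
and all pairwise ratios of scheme means — the mean-ratio reading of
published "times the variance explained" figures, labelled as such.

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` reproduces the statistical structure the analysis
assumes, so every stage has a ground truth:

* two overvaluation items from a latent bivariate normal (target
  correlation 0.80) thresholded to the 0–6 integer grid, hence a 0.5-grid
  composite; the discretisation attenuates the realised correlation
  slightly below the latent target;
* planted severity groups: the latent mean shifts at the
  `true_cutpoints` of the composite (defaults: the published cutpoints
  1.25/3.75/4.75/5.75 with group means −1.2/−0.6/0/0.6/1.2, a strong but
  realistic separation chosen once — the source analysis does not report
  group-level latent means);
* indicators $\lambda\eta + \varepsilon$ ($\lambda = 0.8$, residual
  variances 0.36, so unit within-group indicator variance), mapped to
  instrument-scale totals by stratum-specific affine maps (CESD-like vs
  PHQ-9-like depression scales, OASIS-like vs GAD-7-like anxiety scales);
* anxiety blanked missing-completely-at-random at rate 0.35;
* overdispersed negative-binomial 28-day behavior counts (the count
  distribution is unspecified in the source, only its cap downstream;
  negative-binomial with size 0.6 and means 10/5/12 is a realistic choice
  fixed once), independent of the latent factor — so compensatory
  frequency is an uninformative covariate by construction, the "weak
  behavioral signal" regime;
* default cohort size 1017 (the analytic sample size) with strata
  proportions 45/35/20% residential/PHP/outpatient; item grid location
  4.8 and scale 1.8, giving a lower tail of a few percent below composite
  1.25 and a heavily populated top group, qualitatively like the clinical
  cohort.

Truth (group labels, latent scores) is stored in a sidecar, never in the
analysis CSV. Not emulated: item-level EDE-Q responses (instrument totals
are generated directly, and without ceiling/floor clipping, so they are
idealised continuous scores), MAR/MNAR missingness, treatment response
over time, demographic structure, and any association between
compensatory counts and severity. Passing tests on these cohorts
therefore show that the machinery recovers structure *of the assumed
form*; they cannot show that real BN severity has that form.

## Simulation scales used by the test suite

The acceptance-style checks run at: 50 complete-data fixtures (n = 200)
for the FIML/closed-form oracle agreement (1e-10); 20 cohorts of n = 2000
for parameter recovery (mean absolute error ≤ 0.05); 50 cohorts of
n = 1000 (single cutpoint) and n = 2000 (two cutpoints) for cutpoint
recovery (≥ 90% / ≥ 80%); 200 null cohorts of n = 500 for type-I control
(≤ 7.5% at nominal 5%); 20 replicate 20-tree forests of n = 1000 for the
importance ordering (≥ 95%); and one full default cohort for the
end-to-end scheme ordering. A planted cutpoint that coincides with a grid
value x is recovered as the midpoint between x − 0.5 and x, 0.25 below the
planted value — the closest threshold the data can express.

## Known limitations

* The tree handles numeric covariates with binary threshold splits only —
  no surrogate splits for missing covariates, no multiway categorical
  splits, no cost-complexity pruning.
* The bootstrap confirmation adds (bounded, early-exiting) computation at
  borderline nodes; with `confirm = "chisq"` splits retain slightly too
  often in small nodes.
* Importance values depend on the permutation estimator and resampling
  design; only orderings, not magnitudes, should be compared across
  implementations.
* With three indicators the outcome model's overall fit is untestable by
  construction; conclusions are about *relative* fit across subgroups.
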