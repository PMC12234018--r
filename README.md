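# severitree

Empirical severity-subgroup discovery for bulimia nervosa (BN) with SEM
trees, for clinical researchers who want to know *which* metric best grades
BN severity and *where* its cutpoints lie, rather than assuming the DSM-5
compensatory-frequency bands.

## What it does

Severity is a latent factor $\eta$ measured by three z-scored indicators —
cognitive eating-disorder symptoms (EDE-Q Global without the overvaluation
items), depression, and anxiety — with one shared loading:

$$x_k = m_k + \lambda\,\eta + \varepsilon_k,\qquad
\Sigma = \lambda^2 J + \mathrm{diag}(\mathrm{resid}_1,
\mathrm{resid}_2, \mathrm{resid}_3),\qquad \mathrm{Var}(\eta) = 1,$$

estimated by full-information maximum likelihood (FIML), so records
missing anxiety (about 35% in the motivating cohort) still contribute.
An **SEM tree** recursively splits the cohort on candidate severity
covariates — shape/weight overvaluation (mean of two 0–6 items) and capped
compensatory-behavior frequency — choosing each split by the
likelihood-ratio improvement $2(LL_L + LL_R - LL_{parent})$ under the
**fair criterion**: thresholds are selected on one random half of the node
and the retention decision is a valid test on the other half (with a
parametric-bootstrap calibration for small nodes). An **SEM forest**
(bootstrap resamples, one variable per split) ranks the covariates by
out-of-bag permutation importance in −2 log-likelihood units. The
resulting grouping is compared with three existing severity schemes
(DSM-5 bands, clinical overvaluation "either item ≥ 4", single vs multiple
purging methods) on clinical characteristics via Welch-aware one-way
ANOVAs, orthogonal lower-vs-higher planned contrasts with Cohen's d, and
per-scheme variance-explained (partial $\eta^2$) summaries.

A synthetic-cohort generator reproduces the statistical structure the
analysis assumes (correlated 0–6 item pair, planted latent cutpoints, MCAR
anxiety missingness, overdispersed behavior counts, level-of-care strata),
so the whole pipeline is testable without patient data. See the vignette
`vignettes/severity-discovery.Rmd` for the methods account.

## Worked example

```r
library(severitree)

coh <- generate_cohort(cohort_spec(seed = 42))   # n = 1017, planted cutpoints
dat <- preprocess_cohort(coh)                    # exclusions, composites, z-scores
nrow(dat)
#> [1] 1015

tree <- grow_tree(dat, c("overvaluation", "comp_freq_28d"),
                  tree_config(seed = 43))
tidy(tree)
#> # A tibble: 2 × 8
#>      id depth covariate     value    lr        p    p_adj     n
#>   <int> <int> <chr>         <dbl> <dbl>    <dbl>    <dbl> <int>
#> 1     1     0 overvaluation  4.75 281.  5.98e-57 3.08e-25  1015
#> 2     3     1 overvaluation  5.75  55.3 1.32e- 9 9.83e- 6   554
```

Both retained splits are on overvaluation, none on compensatory
frequency — the tree finds severity cutpoints at composite 4.75 and 5.75
(three groups). The forest agrees about which covariate matters:

```r
forest <- grow_forest(dat, c("overvaluation", "comp_freq_28d"),
                      forest_config(n_trees = 30, vars_per_split = 1, seed = 44))
variable_importance(forest, dat)
#> # A tibble: 2 × 3
#>   covariate     importance  rank
#>   <chr>              <dbl> <int>
#> 1 overvaluation     4832.      1
#> 2 comp_freq_28d       53.6     2
```

Overvaluation contributes ~4800 units of −2 log-likelihood improvement on
out-of-bag data; compensatory frequency is two orders of magnitude behind
(it is uninformative by construction in the synthetic cohort). Comparing
the four severity schemes on the clinical characteristics each does not
define:

```r
cmp <- compare_schemes(dat, assign_schemes(dat, tree = tree))
variance_summary(cmp)$by_scheme
#> # A tibble: 4 × 5
#>   scheme                        min     max    mean n_characteristics
#>   <chr>                       <dbl>   <dbl>   <dbl>             <int>
#> 1 clinical_overvaluation 0.0000588  0.259   0.0787                  5
#> 2 dsm5                   0.000415   0.00725 0.00332                 5
#> 3 purging_count          0.00000139 0.0586  0.0125                  5
#> 4 semtree                0.00153    0.236   0.141                   5
```

Tree-derived groups explain on average 14% of the variance in the
clinical characteristics, versus 8% for binary clinical overvaluation,
1% for purging-method count and well under 1% for the DSM-5 bands — the
severity signal in this cohort lives in overvaluation, and modelling it
beyond a binary cut pays.

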