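# adltraj

Hybrid Markov / distance-based clustering of disability-state trajectories,
with representative-trajectory extraction and survival linkage.

## What problem this solves

Nursing-home residents are assessed repeatedly on nine activities of daily
living — bathing (B), grooming (G), dressing (D), feeding (F), transferring
(S), walking (W), toilet use (T), bowel continence (L), urinary continence
(U). Each assessment is a binary impairment profile, encoded here as a 9-bit
*disability state* (GBW = 4 + 16 + 32 = 52; the no-impairment state is 0; all
nine impaired is 511). A resident's record becomes a sequence of
state-duration *spells*, and the analytic question is: what are the typical
functional-trajectory phenotypes in a cohort, and do they differ in mortality
risk?

Computing all pairwise sequence dissimilarities is infeasible for cohorts of
10^5 residents. `adltraj` implements a three-phase hybrid for analysts of
longitudinal functional-status data:

1. **Phase 1** — a hard-EM mixture of first-order Markov chains
   (`P(x | c) = prod_i P(x_i | x_{i-1}; c)`) cuts the deduplicated,
   frequency-weighted trajectory pool into a few primary clusters.
2. **Phase 2** — inside each primary cluster: optimal-matching-on-spells
   (OMspell) distances with severity-based substitution costs and constant
   INDEL, weighted average-linkage hierarchical clustering, weighted PAM
   initialized from the hierarchical medoids, and a weighted-silhouette
   (ASWw) scan over k = 2..20.
3. **Phase 3** — pool all sub-cluster medoids, reassign every trajectory to
   its nearest medoid (an `n x m` computation instead of `n x n`), then
   iteratively merge the weakest cluster into its nearest neighbor while
   tracking five weighted quality indices (ASWw, Hubert's Somers' D,
   Hubert's C, Calinski–Harabasz, pseudo-R2); a min–max-normalized composite
   selects the final number of clusters.

Each final cluster is summarized by a small representative-trajectory set
(frequency / centrality / density / likelihood criteria, coverage >= 75%, at
most 10 representatives) and linked to mortality via Kaplan–Meier curves and
Cox proportional-hazards models adjusted for baseline age and sex (from the
`survival` package), including sex-stratified and cluster-by-sex interaction
sensitivity analyses.

A configurable synthetic-cohort simulator with known phenotype structure and
cluster-dependent mortality (`simulate_cohort()`, presets `tiny`,
`separated4`, `realistic`) makes every stage testable without access to
restricted clinical data.

## Worked example

```r
library(adltraj)

sim <- simulate_cohort(sim_preset("separated4"), seed = 1)  # 2,000 patients
res <- run_pipeline(sim$records, pipeline_config(seed = 1))
res
#> <adltraj_result> 2000 patients, 1590 unique patterns, k_final=4
```

The cohort has four built-in phenotypes; the pipeline deduplicates 2,000
records into 1,590 weighted patterns and the multi-metric composite peaks at
k = 4 (composite 0.92 at k = 4 vs 0.82 at k = 5 and 0.37 at k = 3 in the
merge trace `res$trace$report`). Per-cluster descriptives:

```r
pool_stats(res$pool, res$final$labels)
#>   cluster   n n_patterns mean_length mean_n_states mean_recurrence
#> 1       1 497        399         631          1.00               1
#> 2       2 491        385         602          1.01               1
#> 3       3 519        404         601          1.00               1
#> 4       4 493        402         621          1.00               1
```

`mean_length` is the trajectory span in days, `mean_n_states` the average
number of distinct states visited, `mean_recurrence` the spells-per-state
ratio (1 = no state revisited; this fixture simulates stable phenotypes).
Mortality differs by cluster (simulated hazards are phenotype-graded):

```r
res$survival$cox
#> <cox_result> survival::Surv(time, event) ~ cluster + age + sex (ties=efron)
#>      term     coef    hr      se      z        p lower upper
#>  cluster2  0.92698 2.527 0.09795  9.463 2.98e-21 2.085  3.06
#>  cluster3  0.27097 1.311 0.10585  2.560 1.05e-02 1.066  1.61
#>  cluster4  0.59816 1.819 0.10165  5.884 4.00e-09 1.490  2.22
#>       age  0.00115 1.001 0.00263  0.436 6.63e-01 0.996  1.01
```

Hazard ratios are relative to cluster 1; age was generated independently of
the hazard, and its HR is correctly ~1. Representatives per cluster
(criterion chosen by coverage/size/gain):

```r
res$representatives[["1"]]$best
#> <rep_set> criterion=likelihood n_reps=3 coverage=0.903 gain=0.43
```

`write_solution(res, "out/")` exports labels, spells, weights, medoids, the
merge trace, representatives and survival tables (CSV/JSON) plus a run
manifest; a thin CLI wraps the same functions:

```sh
Rscript inst/cli/adltraj.R simulate --preset tiny --seed 1 --out cohort.csv
Rscript inst/cli/adltraj.R run-all --input cohort.csv --seed 1 --outdir out/
```

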