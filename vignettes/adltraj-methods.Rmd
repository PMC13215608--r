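---
title: "Hybrid Markov / distance-based clustering of disability trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid Markov / distance-based clustering of disability trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adltraj)
```

## The problem

Long-term-care residents are assessed repeatedly on nine activities of daily
living (ADL): bathing (B), grooming (G), dressing (D), feeding (F),
transferring (S), walking (W), toilet use (T), bowel continence (L) and
urinary continence (U). Each assessment is a binary impairment profile, and a
resident's record is an irregularly timed sequence of such profiles. The goal
is to group residents into a modest number of functional-trajectory
phenotypes — who declines, how fast, through which combinations of
impairments — and to ask whether those phenotypes carry prognostic
information about mortality.

Pairwise sequence dissimilarities are the natural tool for this, but an
`n x n` distance matrix is infeasible for cohorts of 10^5 residents.
`adltraj` implements a hybrid: a cheap model-based stage cuts the cohort into
a few primary clusters, an expensive distance-based stage refines each
primary cluster separately, and a global merging stage repairs the seams.

## State coding and spell sequences

Each assessment is encoded as a 9-bit integer (`encode_state()`), with fixed
bit weights F=1, D=2, G=4, S=8, B=16, W=32, T=64, L=128, U=256. The
weights for F, G, B and W are pinned by published example codes (GBW = 52,
GB = 20, W = 32, all-but-F = 510); the remaining five follow the listing
order of the domains. Encoding is order-insensitive: GBW, GWB and WBG are the
same state.

The observed state is assumed to persist between consecutive assessments, so
a record becomes a sequence of *spells* — maximal runs of one state with a
begin and end day (`build_spells()`). A final one-visit run would have zero
duration, so it is extended by one day: every spell has positive duration.
Because the state space is huge (512 combinations) but heavily skewed, the
clustering alphabet is restricted to the top 25 states by assessment
frequency (`restrict_states()`; ties at rank 25 keep all tied states), either
dropping the remaining assessments or recoding them to a synthetic OTHER
state. Identical spell lists are merged into unique patterns with integer
frequency weights (`merge_identical()`); every downstream computation is
weight-aware, so a weight-`w` pattern behaves exactly like `w` coincident
copies.

## Phase 1 — Markov-mixture primary clusters

`fit_markov_mixture()` fits a `k`-component mixture of first-order Markov
chains to the per-assessment state sequences (self-transitions included, so
duration information survives as self-transition mass) by classification
(hard) EM: assign each pattern to its best component, re-estimate transition
matrices from weighted counts plus `alpha = 0.5` pseudo-counts, repeat.
Three numerical choices deserve a note:

* **Monotone objective.** With smoothing, the quantity hard EM provably
  never decreases is the *penalized* classification log-likelihood
  (log-likelihood plus the Dirichlet term `alpha * sum(log theta)`); that is
  what `loglik_trace` records, and it equals the plain classification
  log-likelihood at `alpha = 0`. Re-seeding an empty component (from the
  worst-fitting sequence) can reset the trace.
* **Initialization.** Hard EM is greedy and has many fixed points. Each
  component is seeded from the smoothed transition counts of a randomly
  drawn pattern, and the fit is restarted `n_init = 10` times, keeping the
  best final objective. Pure random matrices were markedly worse at escaping
  mixed local optima.
* **What hard EM can and cannot separate.** The classification likelihood
  rewards whatever partition best explains transitions. When sequences are
  short (a handful of transitions), a partition by realized dynamics
  ("stayers" vs "switchers") can genuinely beat the generating partition,
  and no optimizer can recover the latter from the likelihood alone. With
  longer sequences the realized dynamics concentrate and support-based
  separation dominates. Tests of phenotype recovery therefore use sequences
  with enough transitions for the truth to be identifiable.

Phase 1 deliberately does not select `k`; the default of 4 primary clusters
is a coarse partition whose only job is to shrink the distance computations.
For the same reason `run_pipeline()` defaults to a *single* run from random
row-stochastic matrices (`phase1_init = "dirichlet"`, `phase1_n_init = 1`):
a likelihood-maximal phase 1 yields very pure primary clusters, which leaves
the phase-2 silhouette scan looking at structureless within-phenotype data
and invites shattering; a coarser mixed partition lets phase 2 see real
boundaries. Standalone model fitting keeps the robust restarted defaults.

## Dissimilarities — optimal matching on spells

`omspell_distance()` is an edit distance on spell sequences: insert or
delete a spell `(x, t)` at cost `c_I + e * (phi(t) - phi(1))`, substitute
`(x, t) <-> (y, u)` at cost `S(x, y) + e * |phi(t) - phi(u)|`. Substitution
costs come from state attributes: by default the severity scheme
`S(x, y) = 2 |sev(x) - sev(y)| / 9`, with a floor of 0.1 for distinct states
of equal severity so no two distinct states are cost-free to exchange; a
Hamming scheme over the nine domains is the alternative. Adjacent same-state
spells are merged before the dynamic program, which makes the distance
invariant to non-canonical input. The module-level defaults are
`c_I = 1`, `e = 0.5`, `phi = identity`, durations in days.

**Scale of the expansion cost.** The three ingredients of the distance live
on very different scales. Substitution costs are bounded by 2; the INDEL
cost is 1; day-denominated durations run into the thousands. With
`e = 0.5`/day, duration terms are two orders of magnitude above the full
substitution range and the metric degenerates into "how long was the
follow-up". The pipeline therefore defaults to `phi = sqrt` with
`e = 0.05` per `sqrt`-day: a typical spell-duration difference (5–10
`sqrt`-day units) is then priced at 0.25–0.5, i.e. one or two severity
levels, keeping sequencing, timing and duration commensurate. (Integer
visit-denominated durations were rejected: they produce exact zero-distance
pattern groups, and the silhouette then rewards unbounded shattering.) Both
choices are plain `pipeline_config()` fields; nothing downstream depends on
them structurally.

Two irreducible features of this geometry are worth knowing when you
interpret clusters: a sequence with one extra spell is at least `c_I` away
from its single-spell neighbours, so spell-count heterogeneity inside a
phenotype will surface as sub-clusters; and follow-up-length differences
always contribute `e * |phi(t) - phi(u)|`, so length strata can, too. These
are properties of optimal matching on spells, not artifacts.

## Phase 2 — hierarchical + weighted PAM inside each primary cluster

Within each primary cluster the square OMspell matrix is computed (C++ core)
and `select_k_by_asww()` scans `k = 2..20`: cut the weighted average-linkage
tree (`stats::hclust` with `members = weights`, i.e. Lance–Williams with
cluster mass equal to summed frequency weights), take the weighted cluster
medoids as initialization, run weighted PAM (`weighted_pam()`,
best-improvement swaps, deterministic tie-breaks), and score with the
weighted average silhouette width (ASWw). The highest ASWw wins, ties to the
smaller `k`.

## Phase 3 — global reassignment, quality-driven merging

The sub-cluster medoids are pooled and every pattern is reassigned to its
nearest medoid (`global_reassign()`), which needs only an `n x m` rectangular
distance block. Then `merge_step()` repeatedly (i) finds the cluster with the
lowest weighted mean silhouette, (ii) merges it into the cluster with the
nearest medoid, (iii) recomputes the merged cluster's weighted medoid and
reassigns everyone. Five weighted quality indices are recorded at every `k`
(`quality_report()`): ASWw, Hubert's Somers' D (rank agreement between
distances and the within/between partition), Hubert's C (within-pair distance
sum against the best achievable sum), Calinski–Harabasz and pseudo-R2 (both
also in squared-distance form). All five are defined by *weight expansion*: a
weight-`w` pattern contributes `choose(w, 2)` zero-distance within-pairs, so
the weighted index equals the unweighted index on the expanded instance —
that equality is the central correctness property in the test suite.

A note on monotonicity: for nested merges R2 can only decrease as `k`
drops, but the reassignment step makes the trace non-nested, and R2 can
tick *up* by a fraction of a percent after a merge. That is the
reassignment improving the partition, not an error.

`select_optimal_k()` min–max normalizes ASWw, CH, Somers' D, pseudo-R2
(squared variants) and `1 - HC` across the trace and maximizes their mean,
ties to the smaller `k`, with an optional interpretability cap. The full
trace is always kept so a human can overrule the composite.

## Representatives

`extract_representatives()` summarizes each final cluster by a few patterns
under four criteria — frequency, centrality (the weighted medoid first),
neighborhood density, and likelihood under the cluster's own smoothed Markov
chain. Candidates are taken in score order, skipping anything within the
neighborhood radius `r = pradius * max(within-cluster distance)`
(`pradius = 0.10`) of an already chosen representative, until weighted
coverage reaches 75% or 10 representatives are used.
`select_best_criterion()` keeps the sets meeting both thresholds and ranks by
gain (distance reduction against the single-medoid baseline, so a lone
medoid scores 0), then set size, coverage, and finally the fixed priority
centrality > likelihood > frequency > density.

## Survival

`survival_table()` gives one row per patient — follow-up from the first
eligible assessment to death or right-censoring — with the final cluster as a
baseline covariate. Kaplan–Meier curves and Cox proportional-hazards models
(Efron ties, cluster 1 as reference, adjusted for baseline age and sex) come
from the `survival` package; `sensitivity_suite()` adds sex-stratified
curves, sex-specific models and a cluster-by-sex interaction model with
per-term Wald p-values. No competing-risks model is fitted; death is the sole
event and other endings are treated as non-informative censoring.

## The synthetic cohort generator

`simulate_cohort()` draws, per patient: a phenotype; visit days (log-normal
gaps, about quarterly by default); a visit-level state path from the
phenotype's Markov chain with geometric spell persistence; baseline age
(normal, mean 71.07, SD 12.26, truncated at 20) and sex (96.9% male); and an
exponential death time whose rate depends only on the phenotype, so
proportional hazards holds by construction. A death drawn before the third
visit is re-drawn from that visit onward (memoryless restart) so that
generated cohorts always pass the exclusion rules. It emulates irregular
visit timing, spell persistence, skewed state usage, duplicate trajectories
and cluster-dependent right-censored mortality; it does *not* emulate
measurement error in the ADL coding, informative censoring, time-varying
hazards, or secular drift — passing recovery tests here says nothing about
those.

Presets:

* `tiny` (n = 60, 2 phenotypes, 4 states) — smoke tests and determinism.
* `separated4` (n = 2,000, 4 phenotypes) — the structure-recovery fixture.
  Each phenotype lives on its own two-state alphabet of a single severity
  (severities 1, 3, 6, 8; the within-pair substitution cost is the
  equal-severity floor, while between-phenotype costs are at least
  `2*2/9`), with strongly diagonal-dominant chains (mean spell 1,000
  visits, 1% leakage to foreign states) and near-regular visits. The design
  makes between-phenotype distances dominate the three irreducible noise
  sources discussed above (length strata, mortality truncation, spell-count
  strata); with weaker persistence or mixed-severity pairs those confounds
  are real distance structure and *no* method could return exactly four
  groups. Mortality rates (1/12000 to 1/4500 per day) are graded across
  phenotypes for the survival linkage.
* `realistic` (n = 20,000, 25 skewed states, dominant mild phenotype) —
  demographic and scale realism.

## Problem sizes used in the test suite

The suite exercises: exhaustive state-code bijection (512 subsets); 200
random spell pairs against a memoized brute-force recursion plus classical
OM and generalized edit-distance reductions; weight-expansion equality of
all five indices on instances expanding to at most 40 rows; hard-EM
monotonicity on 50 random pools and recovery on 600-sequence three-chain
pools over 20 seeds; the full pipeline on ten `separated4` cohorts
(n = 2,000 each); and Cox recovery of a known hazard ratio at n = 2,000.
These sizes keep any single check to a few minutes on one core while leaving
the assertions strict.

## Known limitations

* OMspell substitution costs are bounded by 2, so composition differences
  can never outweigh more than ~2 INDEL units of structural difference;
  clusters in noisy cohorts will partly reflect trajectory length and spell
  count. This mirrors the behaviour of the published framework, whose
  clusters also separate by duration.
* Hard EM gives no uncertainty about the primary partition and its
  component count is fixed by configuration, not selected.
* The multi-metric composite for the final `k` treats the five indices as
  exchangeable after min–max normalization; on data whose hierarchy is
  genuinely deeper than the phenotype level it will prefer the finer
  partition. The merge trace is exported precisely so that this choice can
  be audited.
* The Cox model uses each patient's final cluster as a baseline covariate;
  cluster membership is estimated, and the resulting hazard ratios ignore
  that estimation uncertainty.
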