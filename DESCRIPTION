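Package: adltraj
Title: Hybrid Markov and Distance-Based Clustering of Disability Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters large collections of longitudinal disability state
    sequences built from activities-of-daily-living (ADL) assessments. Nine
    binary impairment domains are encoded as 9-bit disability states, visit
    records are turned into state-duration spell sequences, and identical
    trajectories are merged with frequency weights. Clustering proceeds in
    three phases: a hard-EM mixture of first-order Markov chains forms primary
    clusters; weighted average-linkage hierarchical clustering and weighted
    partitioning around medoids (PAM) on optimal-matching spell (OMspell)
    distances refine each primary cluster with silhouette-driven selection of
    the number of sub-clusters; pooled medoids are then globally reassigned and
    iteratively merged under five weighted cluster-quality indices to select
    the final solution. Representative trajectories are extracted per cluster
    under frequency, centrality, density and likelihood criteria, and cluster
    membership is linked to mortality through Kaplan-Meier curves and Cox
    proportional-hazards models. A configurable synthetic-cohort simulator with
    known phenotype structure and cluster-dependent mortality supports testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
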