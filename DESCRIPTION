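Package: rnaconsensus
Title: Reference-Free Consensus Ranking of RNA 3D Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates and ranks ensembles of RNA 3D structure models without
    an experimental reference. Base-pairing and stacking interactions recurring
    across the ensemble are aggregated into a virtual consensus structure,
    either threshold-based (an interaction must occur in at least n models) or
    conditionally weighted (interactions form a fuzzy set with membership equal
    to their occurrence frequency). Each model is scored against the consensus
    with Interaction Network Fidelity (INF) and the F1-score, adapted to the
    fuzzy setting, optionally under user-supplied secondary-structure
    constraints in extended dot-bracket notation. Includes ranking-similarity
    metrics (Spearman's rho, Kendall's tau, top-k enrichment, rank-biased
    overlap), a Monte-Carlo null model of random rankings with empirical
    confidence intervals, and a noise-injection simulator for robustness
    analysis with Welch tests, Benjamini-Hochberg correction, and Cohen's d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
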