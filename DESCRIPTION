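Package: breathnet
Title: Band-Specific EEG Functional Connectivity Under Paced Breathing and
    Breath-Holding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for block-design EEG experiments contrasting
    self-paced breathing, end-inspiration breath-holding and computer-paced
    breathing. Provides a ground-truth synthetic cohort generator (coupled
    band-limited oscillators with planted phase coupling and a forced vital
    capacity covariate), zero-phase band decomposition, Welch power spectral
    density, Hilbert phase-locking-value connectivity, weighted graph metrics
    (clustering coefficient, local/global efficiency, degree centrality) on
    unthresholded networks, group contrasts with max-T permutation or
    Bonferroni family-wise error control, edge-wise Pearson correlation with
    Benjamini-Hochberg false-discovery control, and three-way condition
    classification via ReliefF feature ranking and a small dense neural
    network with repeated stratified cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
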