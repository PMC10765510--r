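Package: dfcstates
Title: Dynamic Functional Connectivity States and Graph Indicators for
    Stimulation fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (dFC) analysis
    of parcellated fMRI time series, as used to study the network effects of
    intracranial electrical stimulation. Provides windowed and static Pearson
    connectivity matrices, cluster-quality-guided K-means identification of
    recurring connectivity states, state metrics (strength, occupancy rate,
    dwell time, transitions per minute), lobe-level centroid summaries,
    binarized-network graph indicators (clustering coefficient, k-core,
    modularity, assortativity, global and local efficiency) in static and
    per-window dynamic form, nonparametric pre/post comparison
    (Shapiro-Wilk/Levene preconditions, Mann-Whitney U with an exact
    small-sample branch), ADF/KPSS stationarity and FFT periodicity analysis
    of dynamic indicator traces, and a synthetic-cohort generator that plants
    Markov-switching connectivity states with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    car
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
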