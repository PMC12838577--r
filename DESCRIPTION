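Package: spikesync
Title: Synchrony, Community Structure and Plasticity Analysis for
    Multichannel Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing functional network plasticity in
    multi-electrode array (MEA) recordings of cultured neurons. Builds
    binned spike-count synchrony (Pearson) matrices, thresholds them into
    functional graphs, detects subnetworks by Louvain modularity
    maximisation, canonicalises community affiliations into sequences and
    quantifies between-trial network similarity with the Levenshtein edit
    distance. Also provides joint inter-spike-interval and burst firing
    metrics, a network synchronization activity index, exact small-sample
    Mann-Whitney and Wilcoxon signed-rank tests with Z-based effect sizes,
    electrode stimulation charge-safety calculations (Shannon criterion),
    and a Markov-modulated Poisson spike-train generator with planted
    community structure and stimulation-condition effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
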