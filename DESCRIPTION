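Package: chromkin
Title: Stochastic Kinetics of Sister-Chromatid Resolution and Chromosome Compaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the timing of sister-chromatid resolution
    and chromosome compaction from live-cell tracking of two fluorescently
    marked chromosome loci (tetO/lacO operator arrays). Provides a rule-based
    classifier that converts 3D dot-centroid time courses into
    chromosome-configuration states aligned to nuclear envelope breakdown
    (NEBD), a stochastic licensing/transition model of the
    nonresolved -> resolved -> compacted progression simulated over cell
    populations, least-squares model fitting with bootstrap uncertainty,
    per-phase summaries with chi-square comparisons, and a synthetic
    microscopy-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
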