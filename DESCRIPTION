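Package: pairpatch
Title: Analysis of Paired Patch-Clamp Recordings and Neuronal Ensemble
    Formation
Version: 0.1.0
Authors@R:
    person("Ana", "Morales", email = "ana.morales@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analysis of paired
    intracellular patch-clamp recordings from cortical neurons:
    spike detection and phase-plot firing-threshold estimation, F-I
    excitability metrics and rheobase, input resistance from I-V step
    protocols, evoked EPSC/EPSP quantification with paired-pulse ratio
    and monosynaptic connection classification, spontaneous EPSP event
    detection, pairwise correlation of spontaneous activity, and exact
    small-sample nonparametric statistics (Wilcoxon signed-rank,
    Mann-Whitney).  Includes a synthetic-trace generator (exponential
    integrate-and-fire membrane with spike-template splicing,
    Tsodyks-Markram short-term depression, Poisson synaptic barrages
    with shared-input correlation) that emits ground truth so every
    analysis stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
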