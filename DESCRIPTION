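Package: washoutR
Title: Retention Ratios and Wash-Out Dynamics in Aerobic Granular Sludge
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Paired granular-versus-effluent analysis of 16S rRNA amplicon
    count tables from aerobic granular sludge sequencing batch reactors.
    Computes per-taxon retention ratios (granular relative read abundance
    divided by effluent relative read abundance in contemporaneous samples),
    phase-wise one-sample Wilcoxon signed-rank tests against 1 with exact
    tie-aware p-values, temporal trend correlations, Bray-Curtis
    paired-similarity summaries, non-metric multidimensional scaling with
    Kruskal stress-1, and Margalef/Pielou diversity indices. Includes a
    mechanistic two-compartment wash-out simulator with known ground truth
    (proportional wash-out during start-up, surface-biased granule erosion at
    steady state) so every analysis stage can be validated in silico.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, BiocGenerics, vegan, jsonlite
Suggests: testthat (>= 3.0.0), biomformat, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
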