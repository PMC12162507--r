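Package: surrtools
Title: SurR Binding-Motif Scanning, Growth Kinetics and qPCR Quantification
    for Thermococcal Energy-Metabolism Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the pressure- and sulfur-dependent regulation
    of energy-metabolism gene clusters controlled by the redox-sensitive
    transcription regulator SurR in Thermococcales, developed around the
    piezophilic archaeon Thermococcus barophilus. Provides strand-aware
    promoter extraction from genome annotation, exhaustive scanning for the
    gapped SurR consensus motifs (short GTTn3AAC and long GTTn3AACn5GTT) with
    a configurable mismatch and spacer-deviation budget, specific growth-rate
    estimation from cell-count time series across sulfur and hydrostatic
    pressure conditions, delta-delta-Ct relative expression quantification
    with reference-gene stability ranking, and a synthetic-data generator
    that plants motifs, growth rates and expression ratios with
    machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
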