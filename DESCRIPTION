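Package: seromark
Title: Spectral-Count Biomarker Discovery for Paired-Control Serum Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Label-free biomarker discovery from shotgun-proteomics spectral
    counts in paired-control study designs. Implements peptide-spectrum-match
    probability filtering, the two-peptide rule, merging of isoelectric-focusing
    fractions into per-sample protein count matrices, pooled two-group G-tests
    on normalized scan counts, Holm-Sidak step-down adjustment, a candidate
    filter cascade (elevation, fold change, detection frequency), cross
    time-point overlap reports and gene-ontology term tallies. Includes a
    synthetic peptide-spectrum-match simulator emulating a paired serum study
    with spiked treatment effects, so every stage can be exercised end to end
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
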