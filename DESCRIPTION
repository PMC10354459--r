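Package: modreader
Title: Identify Candidate Reader Proteins of Modified RNA from Bait
    Pulldown Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for RNA-bait affinity pulldown mass
    spectrometry screens that search for reader proteins of
    5-methylcytosine (m5C) and its oxidative derivatives (hm5C, hm5Cm,
    f5C). Reads MaxQuant-style proteinGroups tables with per-sample iBAQ
    intensities, performs total-intensity normalization, per-condition
    replicate medians, pseudocount-stabilized fold changes against both a
    beads-only and an unmodified-bait control, calls candidate readers by
    dual fold-change thresholds, derives per-modification unique-binder
    sets with full Venn overlap structure, tests unique binders for
    phenotype-set over-representation (exact hypergeometric with
    Benjamini-Hochberg correction), and flags RRM-characteristic
    RNP1/RNP2 consensus motifs in candidate protein sequences. A
    synthetic-data generator with planted readers and known ground truth
    supports end-to-end benchmarking without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
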