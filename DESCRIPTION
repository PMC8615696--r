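Package: sigreverse
Title: Signature-Matching Drug Repurposing with Reversal Scoring and BBB Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A connectivity-mapping pipeline for transcriptomic drug
    repurposing. Computes characteristic-direction differential-expression
    signatures from replicated treatment/control experiments, calls up- and
    down-regulated gene sets by z-test, scores disease-versus-drug reversal
    with the Jaccard index over a multi-condition signature library
    (best-per-drug, averaged over disease signatures), performs
    hypergeometric mechanism-of-action and gene-set enrichment with
    Benjamini-Hochberg adjustment, and re-ranks candidates by imported
    blood-brain-barrier permeability probabilities. Includes a synthetic
    LINCS-like data generator with planted ground truth so the whole screen
    is testable offline, plus readers and writers for GCT, GMT and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
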