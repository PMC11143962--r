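Package: cloneseed
Title: Clonal Dissemination Analysis for Multi-Site Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the subclonal architecture of multi-site cancers
    from deep tumor-normal sequencing and classifies how the cancer
    disseminated between anatomical sites. Implements tumor-normal somatic
    variant filtering, purity- and copy-number-adjusted cancer cell fraction
    (CCF) estimation, multi-sample mutation clustering, exhaustive clone-tree
    enumeration under the sum (pigeonhole) rule, and classification of the
    dissemination mode (monoclonal, monophyletic polyclonal, or polyphyletic
    polyclonal), seeding direction, and relative mutation time of
    dissemination. Ships a synthetic multi-site tumor simulator with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
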