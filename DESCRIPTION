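Package: heterosim
Title: Mid-Parent Heterosis, Non-Additive Expression and Allele-Specific
    Bias Analysis for Hybrid-vs-Parent Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicated F1-hybrid versus parent
    studies in crops: single degree of freedom mid-parent and F2 contrasts
    from randomized complete block field trials with polynomial row/column
    trend adjustment and studentized-residual outlier screening;
    classification of per-gene F1 expression as additive or non-additive
    (above/below both parents) with cross-location concordance; a
    parent-specific-SNP allele-expression-bias caller with splice-proximity
    masking and replicate-consistency rules; and hypergeometric GO term
    over-representation against an expressed-gene background. Includes
    truth-parameterized synthetic-data generators for every stage so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
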