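Package: varconcord
Title: Concordance of Clinical Variant Interpretations and ACMG-AMP
    Reclassification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares interpretations of protein-variant pathogenicity
    between an expert-curated protein-variant resource (humsavar-style
    three-class tables) and a submission-based clinical repository
    (ClinVar-style five-tier records).  Provides HGVS-style protein-change
    parsing, review-status (star) aggregation of per-submitter records,
    cross-resource variant matching with study filters, harmonized 3x3
    concordance statistics with a post-re-curation projection, an
    ACMG-AMP evidence-combination engine with population-frequency and
    computational-consensus evidence derivation, a synthetic-data
    generator with known ground truth, and a reproducible pipeline
    runner with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
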