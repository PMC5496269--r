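Package: saamp
Title: Ensemble Pathogenicity Scoring and Phenotype Prediction for MPS I (IDUA) Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in silico interpretation of variants in the IDUA gene
    (mucopolysaccharidosis type I). Implements the SAAMP pathogenic index, an
    ensemble score over seven variant-effect predictors (SIFT, PolyPhen,
    I-Mutant, PROVEAN, PANTHER, SNPs&GO, PHD-SNP), a sequential screening
    funnel with per-stage survivor counts, benchmark evaluation with
    sensitivity/specificity, a curated knowledge base of IDUA mutation
    severities with rule-based diallelic genotype-to-phenotype prediction,
    functional flagging of UTR variants, a legacy mutation-nomenclature
    parser, and a synthetic benchmark generator. Ships machine-readable
    transcriptions of the published score and severity tables and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
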