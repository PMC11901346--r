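Package: sdldlmed
Title: Mediation of LDL-Cholesterol-Transcriptome Associations by Small Dense LDL
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow linking plasma LDL-cholesterol (LDL-C) to whole-blood
    mRNA expression and quantifying how much of each association is attributable to
    small dense LDL particles (sdLDL). Implements tertile-extremes differential
    expression with per-gene negative binomial generalized linear models and
    likelihood ratio tests, TMM library-composition normalization with
    counts-per-million filtering, a three-condition mediation screen with a
    proportion-mediated statistic, sex-stratified mediation, and hypergeometric
    gene-set over-representation analysis. Ships a calibrated synthetic cohort
    generator with planted direct and mediated effects and known ground truth, so
    every stage of the pipeline is testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    MASS
Config/testthat/edition: 3
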