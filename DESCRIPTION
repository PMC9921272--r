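Package: bcnamScreen
Title: Genomic Screening of Backcross Introgression Lines in Testcross Hybrid Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating backcross nested-association mapping (BC-NAM)
    introgression lines in hybrid combination with elite testers.  Provides a
    gamete-level simulator of BC1F3 populations and testcross trials,
    per-environment REML variance-component analysis with repeatability and
    BLUE extraction, additive (VanRaden) and dominance (Vitezica) genomic
    relationship matrices with Kronecker hybrid kernels, an eigenbasis Gibbs
    sampler for additive-plus-dominance GBLUP, and the CV1/CV3
    cross-validation schemes with selection-accuracy metrics used to judge
    genomic prescreening of introgression germplasm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
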