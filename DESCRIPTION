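Package: mrsevo
Title: Multiregion Tumor Evolution Analysis for Metastatic Neuroendocrine Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multiregion whole-exome sequencing of
    metastatic pancreatic neuroendocrine tumors. Provides binomial-test
    somatic variant calling and filtering, cancer cell fraction and
    clonality estimation, intratumor-heterogeneity statistics (MATH, TMB,
    public/shared/private sharing classes), homologous-recombination
    deficiency scar scores (LOH, TAI, LST) and whole-genome duplication
    calls, de novo mutational signature extraction by non-negative matrix
    factorization with cophenetic rank selection and cosine deconvolution,
    per-patient phylogeny reconstruction (neighbor joining and maximum
    parsimony with bootstrap), metastasis-selected event detection, and
    dissemination-timing inference by approximate Bayesian computation over
    a branching-process growth model. A synthetic multiregion cohort
    generator with full clonal ground truth supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    survival,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
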