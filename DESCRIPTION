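Package: pedsur
Title: Bayesian Bivariate Variable Selection for Longitudinal Traits in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint Bayesian modeling of two quantitative traits measured
    longitudinally in family studies. Bivariate family- and subject-level
    random effects capture within-pedigree and within-subject correlation,
    visit-level residuals of the two traits are correlated as in seemingly
    unrelated regressions, and candidate single-nucleotide variants enter
    through a spike-and-slab prior whose Beta-Bernoulli inclusion layer
    provides intrinsic multiplicity correction. Includes a gene-dropping
    pedigree simulator with known truth, posterior-inclusion-probability
    inference and median-probability-model selection, antihypertensive
    medication adjustment, linkage-disequilibrium utilities, and the
    univariate-Bayes and measured-genotype (mixed-model scan) comparators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'pedsur-package.R'
    'AllClasses.R'
    'chains-io.R'
    'comparators.R'
    'io.R'
    'posterior.R'
    'preprocess.R'
    'sampler-chain.R'
    'sampler-updates.R'
    'simulate.R'
    'validate.R'
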