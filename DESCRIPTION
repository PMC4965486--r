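Package: gsmarker
Title: Genomic Selection with Marker Preselection for Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ridge-regression BLUP genomic prediction for inbred line panels,
    together with the surrounding analysis stages: simulation of structured
    SNP panels and multi-location phenotypes, genotype quality control
    (missing-rate filtering, mean imputation, MAF and PIC), REML variance
    components and broad-sense heritability for the two-way random model,
    best linear unbiased estimates of line means, pairwise linkage
    disequilibrium with D-prime confidence intervals and Gabriel-style
    haplotype-block detection, LD-decay curves, principal-component analysis
    of population structure, five-fold cross-validation with
    heritability-standardized accuracy, and random, haplotype-block-based
    and evenly-spaced marker subsampling over density grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
RoxygenNote: 7.3.3
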