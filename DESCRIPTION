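Package: wgsblup
Title: Genomic Prediction with Dense Marker Panels: GBLUP, Mixed-Model
    GWAS, LD Pruning and Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for genomic prediction with dense (sequence-level)
    marker panels in pedigreed livestock populations. Builds VanRaden
    genomic relationship matrices, estimates variance components by
    restricted maximum likelihood (AI-REML), predicts genetic values by
    GBLUP via Henderson's mixed model equations, runs mixed-linear-model
    association (MLMA) scans, prunes markers by windowed linkage
    disequilibrium, pre-selects variants around association signals, and
    evaluates predictive ability by repeated cross-validation. Includes a
    pedigree-based population simulator (half/full-sib families, tunable
    LD, additive QTL architectures, pen effects, genotype-error and
    masking models) so every stage is testable without external data, plus
    readers and writers for PLINK and VCF genotype formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GenotypeData-methods.R'
    'evaluation.R'
    'gblup.R'
    'genotypeIO.R'
    'grm.R'
    'ld.R'
    'mlma.R'
    'qc.R'
    'reml.R'
    'selection.R'
    'simulate.R'
    'utils.R'
    'wgsblup-package.R'
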