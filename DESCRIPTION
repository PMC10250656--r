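Package: dytburden
Title: Rare-Variant Prioritization and Burden Testing of Dystonia-Related Genes in Parkinson's Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate-gene rare-variant analysis of dystonia-related (DYT)
    genes in case-control Parkinson's disease cohorts. Provides
    inheritance-model-aware variant prioritization (recessive homozygous and
    putative compound-heterozygous states; dominant heterozygous states),
    control-carrier screening, a configurable reduced ACMG evidence engine,
    PLINK-style runs-of-homozygosity detection, and a gene-level SKAT-O
    burden scan over variant subgroups (missense, damaging missense,
    loss-of-function, deleterious at two allele-frequency thresholds) with a
    logistic null model adjusted for age, sex, and principal components.
    Includes a synthetic cohort generator producing VCF, annotation, and
    sample tables with spiked per-gene effects for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
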