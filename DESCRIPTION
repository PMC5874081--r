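Package: degOverlap
Title: Signed Gene-Set Overlap Meta-Analysis with Monte Carlo Null
    Calibration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Meta-analysis of signed differentially-expressed-gene (DEG)
    lists against each other and against binary chromatin annotation
    tracks such as gene-body H2A.Z enrichment and H3K9 acetylation.
    Provides hypergeometric upper-tail overlap tests computed in log
    space, directional overlap partitions (concordant up/down and
    discordant classes), stratified overlaps against intersections of
    annotation tracks, Fisher exact enrichment with Benjamini-Yekutieli
    correction, Monte Carlo calibration of overlap p-values against an
    empirical null built from random gene-list pairs, and the two-factor
    interaction ANOVA and Student's t-tests used for
    genotype-by-environment phenotype analysis. A seeded synthetic-data
    generator produces gene universes, annotation tracks with controlled
    pairwise overlap, signed DEG lists with planted track enrichment and
    tunable cross-list direction concordance, and balanced two-factor
    phenotype tables, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'gene-sets.R'
    'overlap.R'
    'null.R'
    'phenotypes.R'
    'generate.R'
    'pipeline.R'
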