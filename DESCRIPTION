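Package: rbtnseq
Title: Fitness Estimation and Essentiality Calling for Randomly Barcoded
    Transposon Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of pooled fitness assays with randomly
    barcoded transposon mutant libraries (RB-TnSeq/BarSeq). Calls essential
    genes from transposon insertion density and read statistics, estimates
    per-gene fitness as the weighted average of strain log2 abundance ratios
    with running-median and mode normalization along the chromosome,
    computes a t-like significance statistic, and derives downstream
    phenotype analytics: significant phenotypes with a Time0-based false
    discovery rate, condition-specific phenotypes, and cofitness networks.
    Includes a synthetic-data generator that emulates a barcoded insertion
    library with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'config.R'
    'accessors.R'
    'simulate.R'
    'essentiality.R'
    'fitness.R'
    'phenotypes.R'
    'io.R'
    'cli.R'
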