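Package: ModifierScan
Title: Modifier-Locus Discovery in Two-Strain Mouse Crosses with a Survival Phenotype
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for mapping genetic modifiers of a
    binary survival phenotype in an experimental cross between two inbred mouse
    strains. Simulates a multi-generation intercross followed by a terminal
    cross to heterozygous mutant males (Haldane map function, Poisson crossover
    process), stratifies survival records into extreme-phenotype cases and
    controls, runs an ordered SNP quality-control cascade, prunes markers by
    pairwise linkage disequilibrium, performs a sex-adjusted logistic genome
    scan with Bonferroni-over-blocks significance, delineates the significant
    region, and triages candidate genes by aorta expression and
    predicted-deleterious variation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
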