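Package: eccdnaCharter
Title: Characterization and Outcome Association of Extrachromosomal Circular DNA Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize catalogs of extrachromosomal circular DNA
    (eccDNA) intervals called from circle-seq data and to relate eccDNA burden
    to genome instability, expression programs and patient outcome. Provides
    readers for Circle-Map style BED catalogs, genome FASTA and annotation
    tracks; per-sample abundance and size statistics; per-megabase density
    correlations against gene and Alu content; GC profiling of eccDNA loci
    against flanks and a length-matched random-genome background;
    genome-composition-normalized element mapping ratios; the weighted genome
    instability index (wGII) from copy-number segments; non-negative matrix
    factorization grouping of samples into high and low eccDNA-abundance
    strata; group differential expression, single-sample gene-set enrichment
    scoring, optimal-cutoff Kaplan-Meier survival comparison and marker ROC
    analysis. A synthetic-data generator plants every assumed statistical
    structure with truth tables for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    survival,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
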