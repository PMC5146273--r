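Package: mutacc
Title: De Novo Mutation Calling and Rate Estimation for Mutation
    Accumulation Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying de novo mutations in mutation
    accumulation pedigrees from per-position base-count matrices.
    Positions are classified by mutant-allele frequency thresholds,
    candidate mutations are filtered against a background cohort of
    sibling genomes, and accepted mutations are normalized to
    per-generation, per-site rates over accessible sites.  Accepted
    mutations can be characterized by substitution spectrum, local
    sequence context, genomic fraction (gene, transposon, intergenic),
    coding effect, cytosine methylation status, and germline timing
    (heterozygous:homozygous segregation ratios, reciprocal-cross
    parent-of-origin counts).  A synthetic-data generator emulates a
    small annotated diploid genome with a cytosine methylome,
    spontaneous and UV-B-like mutational processes, Poisson sequencing
    coverage with base errors, and selfing or reciprocal-cross
    inheritance, so the caller can be validated end-to-end with
    spike-in simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
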