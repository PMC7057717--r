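Package: wssgblup
Title: Single-Step Genomic Evaluation and Weighted Single-Step GWAS for
    Composite Beef Cattle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-step genomic BLUP (ssGBLUP) evaluation and
    weighted single-step genome-wide association (WssGBLUP) scans in
    composite beef cattle populations such as the Montana Tropical
    Composite.  Builds pedigree (A), genomic (G) and combined (H) inverse
    relationship matrices with tau/omega scaling, fits animal models with
    a breed-heterozygosity covariate by average-information REML, back-
    solves SNP effects from genomic breeding values with iterative SNP
    re-weighting, scans five-SNP moving windows for the proportion of
    genetic variance explained, and annotates significant regions with
    positional candidate genes.  Includes a gene-dropping simulator of
    multi-breed composite populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
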