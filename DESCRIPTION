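Package: pepbsa
Title: Bulked Segregant Analysis of Pepper Immature Fruit Color
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for QTL-seq style bulked segregant analysis (BSA-seq) of
    immature pepper fruit color: per-site SNP/InDel-index and Euclidean-distance
    statistics with sliding-window aggregation, LOESS smoothing and quantile
    thresholding for candidate-interval calling; a forward simulator of an F2
    population segregating for a two-locus green-fruit trait with dominance,
    extreme-bulk selection and binomial read-depth sampling; coding-sequence
    consequence annotation (premature stop codons with truncated protein
    lengths); and the phenotype statistics layer (2G-R-B green index,
    chlorophyll quantification from 649/665 nm absorbance, grade-distribution
    normality reports, genotype-by-grade tables and accession association).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
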