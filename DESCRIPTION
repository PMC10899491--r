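Package: bulkmapr
Title: Bulked-Segregant QTL-seq Mapping with ED and Delta SNP-Index Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for QTL-seq bulked-segregant analysis (BSA) of biparental
    crosses. Reads four-sample VCFs (two parents plus low/high phenotypic
    bulks), applies the staged variant filters used in QTL-seq studies
    (quality, InDel proximity, variant clusters, biallelic, bulk depth,
    parent consistency), and computes two pooled allele-frequency association
    statistics along the genome: the Euclidean-distance (ED) statistic raised
    to the fifth power with a distance-weighted fitted curve and a
    median + 3 SD threshold, and the delta SNP-index with simulated null
    confidence bounds. Candidate regions are called on a 10-kb grid and
    combined with interval algebra (intersection across marker types and
    algorithms, union across traits, chromosome exclusion, per-region gene
    counting). A forward simulator of F2/F3 bulk-segregant experiments with
    extreme-tail pooling and pooled read sampling provides ground-truth data
    for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
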