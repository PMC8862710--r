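Package: genarch
Title: Genome Architecture Landscapes: Tandem Repeats, Organelle
    Insertions, SNP Density and Mapping-Population Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed landscape analyses for chromosome-level plant genome
    assemblies. Canonicalizes tandem-repeat monomers across rotation and
    strand to call telomeric arrays and centromeric satellite clusters;
    builds nuclear insertion events of chloroplast and mitochondrial DNA
    from alignment hits, with length tiers, per-window counts and
    integration anomalies (hotspots, tandem-like clusters, end-proximal
    and co-localized insertions); classifies SNP sites by allele balance
    and maps density anomalies (low-heterozygosity stretches, decoupled
    genic/intergenic windows, repeat-rich and duplicated-gene regions);
    and implements mapping-population utilities (1:1 segregation
    chi-square filtering and Mendelian-exclusion paternity assignment).
    Includes a deterministic synthetic-genome generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
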