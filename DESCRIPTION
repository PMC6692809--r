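Package: chloropop
Title: Chloroplast Population Genomics for Rice Domestication Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled toolkit for haploid organelle population
    genomics, built around the chloroplast genomes of cultivated and wild
    rice. Reads and filters multi-sample VCFs of chloroplast variants,
    computes windowed nucleotide diversity, Weir-Cockerham weighted FST,
    Tajima's D, PCA and MDS ordinations, diversity-reduction selection
    scans, statistical-parsimony (TCS) haplotype networks, subgroup-specific
    allele-frequency introgression scans, heterozygosity-excess bottleneck
    tests under IAM/TPM/SMM mutation models, and Nei-Gojobori (1986) Ka/Ks
    with Jukes-Cantor correction. Includes coalescent-based synthetic-data
    generators so every stage is testable against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    ape,
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
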