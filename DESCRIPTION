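Package: trnldiet
Title: Diet Metabarcoding Analysis with the Chloroplast trnL P6 Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for DNA-metabarcoding diet
    analysis of herbivorous and frugivorous animals from fecal samples,
    built around the chloroplast trnL (UAA) intron P6 loop amplified with
    the universal g/h primers. Builds a local P6-loop reference database
    from full intron sequences, collapses it into haplotype groups labelled
    at the lowest covering taxonomic rank, and reports species-, genus- and
    family-level discrimination rates. Processes MID-tagged amplicon reads
    (demultiplexing, primer trimming, dereplication, 98 percent-identity
    greedy centroid clustering, length and abundance filtering), assigns
    clusters to haplotype groups by best alignment score with
    lowest-common-ancestor tie resolution, and summarizes diets as
    frequencies of reads and of presence, per-sample richness, and monthly
    composition. Community comparisons include Pearson chi-square tests,
    abundance-based Chao-Jaccard dissimilarities, nonmetric
    multidimensional scaling, and ANOSIM permutation tests. A synthetic-data
    module generates taxonomies, reference databases, skewed multi-taxon
    diets and error-bearing tagged reads with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
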