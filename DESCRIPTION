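Package: opsinconv
Title: Gene Conversion and Purifying Selection in Tandemly Duplicated Opsin Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for nucleotide variation in tandemly duplicated
    L and M cone opsin genes. Classifies L/M/hybrid genotypes from the three
    spectral-tuning residues (180, 277, 285) with an additive peak-absorbance
    model; computes within-group nucleotide diversity and between-paralog
    divergence partitioned by exon, intron, synonymous and non-synonymous
    site classes (Nei-Gojobori pathway counting, bootstrap standard errors,
    one-tailed Z comparisons); builds among-group neighbor-joining trees from
    Jukes-Cantor corrected divergences with bootstrap supports; detects gene
    conversion tracts between paralogs with a Sawyer-style maximal-run
    statistic and a permutation-based, multiplicity-corrected global P value;
    and contrasts fixed inter-paralog differences against within-species
    polymorphism by site class (Fisher's exact test, McDonald-Kreitman, HKA,
    D' linkage disequilibrium). A forward simulator of a duplicated gene pair
    evolving on a species tree with mutation, interlocus gene conversion and
    purifying selection at the tuning residues provides ground truth for
    power and calibration studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
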