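Package: hemiclone
Title: Detection of Hemiclonal Subgenomes from Co-Dominant Marker Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting clonally transmitted (hemiclonal) subgenomes
    in diploid hybrid populations from co-dominant marker genotypes such as
    microsatellites. Implements species-specific allele registries, taxon
    assignment and a supervised hybrid-index estimator, partitioning of hybrid
    genotypes into parental haploid subgenomes, Hardy-Weinberg screening with
    null-allele estimation and correction, multilocus-genotype indexing with
    missing-data-aware clone merging, round-robin F_IS, P_GEN/P_SEX clonality
    statistics, Nei DA distances with UPGMA trees and locus bootstrap, allele
    frequency PCA, and a synthetic-data generator for hybridogenetic population
    systems with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
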