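Package: straintrack
Title: Strain-Resolved Tracking of Gut Bacteria in Longitudinal Metagenomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to follow bacterial strains through longitudinal shotgun
    metagenomes of host cohorts. Per-sample core-gene genotypes are
    reconstructed from allele-count pileups (consensus calling with
    conspecific-strain filtering and alignment sanitation), placed on
    intraspecific phylogenies, and partitioned into strains by three
    delineation rules. From strain assignments the package computes
    persistence, resilience and Kaplan-Meier annual survival per host and
    species, family association and vertical/horizontal transmission,
    phylogeography (Mantel correlograms on great-circle distances,
    per-country perMANOVA), population-genetic summaries (Watterson's theta,
    nucleotide diversity, Tajima's D at 4-fold/0-fold degenerate sites,
    Nei-Gojobori dN/dS against an outgroup, Sackin tree imbalance), and a
    clustering of genera into dispersal strategies. A synthetic-cohort
    simulator with Markov strain replacement, family and geographic
    transmission, neutral sequence evolution and read-sampling noise makes
    every stage testable without access to raw sequencing data. Co-abundance
    gene-catalog decluttering and genome-bin refinement utilities are
    included for upstream matrix curation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    survival,
    geosphere,
    seqinr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
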