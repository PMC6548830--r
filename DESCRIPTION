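Package: hybridmosaic
Title: Characterization of Interspecies Hybrid Yeast Genomes
Version: 0.1.0
Authors@R: person("Olive", "Genomics Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing homoploid interspecies hybrid genomes
    shaped by loss of heterozygosity, modelled on Saccharomyces cerevisiae x
    S. paradoxus hybrids. Detects foreign-origin ORFs from competitive
    per-ORF read coverage, segments the sub-genome mosaic with sliding-window
    divergence, builds site-occupancy-filtered SNP matrices for phylogenomics,
    and estimates tandem-array copy number (ENA/CUP1-like genes) from read
    depth with a control-gene calibration. Includes a synthetic
    hybridization-then-LOH simulator with truth tables, and a diagnostic
    k-mer read assigner standing in for competitive mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
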