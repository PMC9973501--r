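Package: nucleoFold
Title: Coupled Nucleosome-Occupancy / Chromatin-Contact Polymer Simulation
    and MNase-Titration Accessibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the interplay between distant chromatin contacts
    and nucleosome occupancy. Implements a coarse-grained bead-spring
    chromatin polymer in which every bead carries a two-state nucleosome
    variable, sampled by Metropolis Monte Carlo with coupled displacement and
    assembly/disassembly moves; observables include mean nucleosome density,
    per-bead occupancy profiles, radius of gyration, and weak inter-nucleosome
    contact counts, with drivers for phase-diagram sweeps and two-region
    heteropolymer experiments. Also implements an MNase-titration-seq
    analysis pipeline: fragment QC, hotspot masking, fixed-width binning,
    reads-per-million normalisation, titration-averaged nucleosome occupancy,
    MACC accessibility scores (per-bin regression slope across the titration
    with GC correction), differential accessibility, and aggregation around
    binding sites, scaled gene bodies and contact regions. A synthetic-data
    generator with known per-bin ground truth makes every pipeline stage
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
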