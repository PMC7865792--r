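Package: chromoblock
Title: DNA-Sequence-Based Block-Copolymer Simulation of Chromatin Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained block-copolymer modelling of interphase chromatin at
    100-kbp resolution. Maps genomic interval tracks (CGI-rich "forest" and
    CGI-poor "prairie" domains, lamina-association signal, TAD boundaries,
    centromere masks) onto bead annotations, builds a bead-spring force field
    (FENE backbone, type-dependent truncated-shifted Lennard-Jones pair
    attractions, harmonic TAD-boundary bonds, spherical confinement with
    lamina-associated-domain wall attraction), runs Langevin dynamics with a
    simulated-annealing protocol, exports LAMMPS input, and computes the full
    observable suite: ensemble contact maps, contact probability versus genomic
    distance with regime-wise power-law fits, domain-resolved contact curves,
    radial density profiles, windowed Fourier spectra of the contact diagonal,
    and intra- versus inter-chromosome contact statistics. A synthetic
    annotation generator reproduces the block statistics of real chromosomes so
    the whole pipeline is testable without genomic data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
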