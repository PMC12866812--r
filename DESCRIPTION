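Package: dnastore
Title: Constrained DNA Sequence Codecs and Physics-Based Randomness
    Assessment for DNA Data Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes binary payloads into synthesis-friendly DNA sequences
    under run-length-limited randomized design rules (the R_N-B# family:
    big-integer radix conversion followed by context-dependent monomer or
    dimer emission with homopolymer constraints), decodes them losslessly,
    and packages payloads into primer-flanked sequencing-ready strands.
    Sequence randomness is quantified with three physics-based models:
    translational and rotational active-particle trajectories with
    MSD/MSAD fits of velocity and diffusion coefficients, mean-field
    inverse-Ising polarization, interaction and bias factors of the spin
    lattice derived from the sequence, and 3-input/1-output logic-scan
    statistics with RMS summaries. Includes an elementary cellular
    automaton fixture generator and PBM image handling for test payloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    png,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'apt.R'
    'bits.R'
    'ruleTables.R'
    'codec.R'
    'strands.R'
    'seqstats.R'
    'logic3.R'
    'fixtures.R'
    'ising.R'
    'assess.R'
    'dnastore-package.R'
    'methods.R'
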