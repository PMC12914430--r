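Package: prmflow
Title: Design, Scheduling, Real-Time Alignment Emulation and Calibration
    Figures of Merit for Multiplex Targeted PRM Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds highly multiplex parallel reaction monitoring (PRM)
    assays from chromatogram libraries: in-silico tryptic digestion and
    cross-species shared-peptide bookkeeping, precursor refinement by peak
    quality and transition interference, cycle-time-constrained retention
    time scheduling with optimized acquisition windows and multi-injection
    splitting, an emulation of adaptive real-time retention-time alignment
    against a compressed reference map, matrix-matched calibration curve
    figures of merit (LOD/LOQ with bootstrap and transition-subset
    optimization), and downstream differential abundance statistics. A
    synthetic chromatogram generator with known ground truth makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
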