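Package: chromassemble
Title: In Silico Chromatin Reconstitution by Coarse-Grained Brownian Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates the self-assembly of 10-nm chromatin fibres from a
    torsionally rigid bead-and-patch DNA polymer and rigid histone-octamer
    cores carrying a left-handed helical path of minor-groove binding sites.
    Includes overdamped Langevin (Brownian) dynamics with a mapped physical
    time scale, staged reconstitution protocols (tetramer to octamer
    switch-on, topoisomerase-I/II-like interventions via twist relaxation or
    soft-core strand passing), twist/writhe/linking-number bookkeeping,
    a defect taxonomy for mis-assembled nucleosomes, simulated micrococcal
    nuclease digestion with gel rendering, planar flattening, and AFM-style
    fibre statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
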