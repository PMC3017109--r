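Package: ienm
Title: Interpolated Elastic Network Models for Conformational Transition Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modelling of large conformational transitions in
    proteins from C-alpha elastic network models (ENM). Builds harmonic
    networks from PDB structures, performs sparse normal mode analysis with
    overlap diagnostics, generates saddle-point transition pathways between
    two superposed end-state conformations by minimising a linearly
    interpolated double-well potential with a steric collision penalty,
    quantifies the motional order of residues along a pathway (fractional
    progress and crossover analysis, motif averages, comparison with
    experimental Phi values), re-runs pathways with selected spring sets
    masked to probe which interactions dictate the order of events, and
    profiles channel pore radii along a pore axis. Ships a synthetic
    two-state structure generator so the full workflow runs without
    downloads, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    bio3d,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
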