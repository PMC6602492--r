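Package: nadock
Title: FFT-Based Rigid-Body Docking of Nucleic Acid Structures
Version: 0.1.0
Authors@R:
    person("nadock", "developers", email = "nadock@example.org", role = c("aut", "cre"))
Description: Global rigid-body docking of RNA and DNA structures. Binding
    modes of one nucleic acid relative to another are sampled exhaustively by
    correlating shape-complementarity grids over all translations with fast
    Fourier transforms, for a deterministic set of evenly distributed
    rotations. Candidate poses are rescored with a distance-dependent
    knowledge-based atom-pair potential, filtered against optional
    binding-site or distance restraints, clustered greedily by ligand RMSD,
    and written out as ranked PDB models. Includes interface-RMSD based
    evaluation against a native complex, a synthetic A-form duplex generator
    so the whole pipeline is testable without external data, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
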