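Package: rotbh
Title: Sequence-Dependent Rotamer Libraries and Rotamer-Move Basin-Hopping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequence-dependent, backbone-independent rotamer libraries
    from conformational ensembles of capped tripeptides by average-linkage
    agglomerative clustering of side-chain chi dihedrals under a periodic
    torsional metric, with occupation probabilities taken from Boltzmann
    equilibrium populations at 298 K.  The resulting libraries drive rotamer
    moves in basin-hopping global optimization, alongside group-rotation and
    Cartesian-displacement moves, with either potential-energy or harmonic
    local free-energy (FEBH) acceptance.  Includes torsional geometry
    utilities, library serialization and coverage reporting, desk-scale toy
    potentials with enumerable global minima for benchmarking move schemes,
    and multi-model PDB input/output.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
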