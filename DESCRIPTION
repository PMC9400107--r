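Package: taamkit
Title: Transferable Aspherical Pseudoatom Data Banks: Atom Typing,
    Multipole Densities and Structure-Factor Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and applying pseudoatom data banks in the
    Hansen-Coppens multipole formalism, as used by the transferable
    aspherical atom model (TAAM) of small-molecule and macromolecular
    crystallography.  Provides a line-oriented text format for atom-type
    entries (colored connectivity graph, local coordinate system,
    point-group symmetry label and averaged multipole populations),
    covalent connectivity and ring/planarity perception for structures
    read from XYZ, small-molecule CIF and SHELX res files, atom typing by
    colored graph-subgraph isomorphism, evaluation of pseudoatom electron
    densities and valence-only structure factors with closed-form
    Fourier-Bessel transforms of Slater radial functions, least-squares
    recovery of multipole parameters from theoretical structure factors,
    and the averaging pipeline that turns per-atom parameter sets into
    transferable atom-type entries with transferability diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
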