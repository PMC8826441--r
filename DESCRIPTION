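Package: fglattice
Title: Functionally Graded Lattice Implant Design by Homogenization and
    Genetic Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing functionally graded truss-lattice implants
    such as acetabular reinforcement cages. Computes effective elastic
    properties of octet-truss, body-centred and face-centred unit cells by
    unit-test-strain homogenization on voxelized representative volume
    elements; fits polynomial density-property surrogates; maps CT Hounsfield
    values to heterogeneous bone material; solves linear elasticity on
    hexahedral macro meshes; minimizes structural compliance under a volume
    constraint with a binary-coded, element-wise genetic algorithm subject to
    additive-manufacturing and bone-ingrowth constraints; and exports the
    optimized graded lattice as printable STL geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
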