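Package: hookjoint
Title: Geometric Analysis of Supercoiled Flagellar Hook Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the geometric analysis of helical polymer assemblies
    such as the bacterial flagellar hook in its native supercoiled form.
    Provides helical-lattice indexing of subunits (1-start ordering, -5/6/11
    start neighbour maps, protofilament assignment), per-residue axial
    spacing profiles that quantify protofilament compression and extension,
    Kabsch superposition with rigid-domain shift and tilt decomposition,
    discrete curvature/torsion estimation and least-squares helix fitting of
    the tube centerline to recover supercoil pitch, radius and handedness,
    inter-subunit contact classification and per-residue neighbour-distance
    variability, and a coarse-grained generator of straight and supercoiled
    11-protofilament assemblies with known ground truth for parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
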