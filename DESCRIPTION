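Package: aldipose
Title: Reactive-Pose Analysis of PLP External-Aldimine Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of external-aldimine conformational
    ensembles from PLP-dependent decarboxylases. Reads multi-model PDB
    ensembles, measures the four reactive-pose descriptors (the
    proton-transfer distance d1 and angle theta1, the scissile-bond
    alignment dihedral chi1, and the cofactor-protonation distance d2),
    classifies reactive binding poses against substrate-specific threshold
    windows, builds and prunes covalent-ligand rotamer libraries by
    dihedral perturbation, classifies catalytic-lysine ammonium
    conformations (MC1-MC3), and correlates per-variant reactive-pose
    statistics and docking scores with measured decarboxylase activities.
    Includes a synthetic-data generator that constructs aldimine fragments
    with prescribed descriptors, ensembles with known reactive fractions,
    and variant panels with a stated activity model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
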