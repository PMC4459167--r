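Package: fibrilkit
Title: Hydrogen Bonding, Adhesion and Mechanics of Cell-Wall Polymer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis layer for atomistic models of plant cell-wall
    polymers (lignin, hemicellulose, lignin-carbohydrate complex, and
    cellulose substrates): geometric hydrogen-bond detection with
    12-10 CHARMM/DREIDING-style energetics and cooperativity chains,
    pairwise Lennard-Jones plus Coulomb energy decomposition and
    interfacial adhesion per unit area, radial distribution functions
    and axial concentration profiles, virial-stress Young's moduli from
    affine strain series, glass-transition breakpoint fitting of
    specific-volume cooling curves, and rule-of-mixture composition
    algebra. Ships synthetic-configuration generators with
    oracle-computed ground truth so every stage is testable without
    external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
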