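Package: cgslide
Title: Coarse-Grained Simulation and Analysis of Protein Facilitated
    Diffusion on DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structure-based coarse-grained models of DNA-binding
    proteins (one bead per residue at the Calpha position) and duplex DNA
    (three beads per nucleotide at the sugar, base and phosphate group
    centers), evaluates a Go-type force field with 12-10 native contacts,
    excluded volume and Debye-Hueckel electrostatics, and propagates the
    system with underdamped Langevin dynamics. Trajectories of a binder
    diffusing along DNA are classified frame by frame into three-dimensional
    diffusion, rotation-coupled major-groove tracking and rotation-decoupled
    hopping, with flip detection for dimeric binders. Mean-square-displacement
    estimators return translational and rotational diffusion coefficients,
    the helical pitch of sliding, and a hopping-augmented one-dimensional
    diffusion coefficient. Synthetic generators provide ideal straight and
    bent B-DNA, a toy dimeric binder with a positively charged recognition
    face, and labelled oracle traces for validating the event classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
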