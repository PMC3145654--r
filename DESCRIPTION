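Package: cgcam
Title: Coarse-Grained Calmodulin Simulation and Thermal-Unfolding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-bead-per-residue coarse-grained model of calmodulin with
    Debye-Hueckel screened electrostatics, calcium beads attached to the
    EF-hand ligand residues, hard-sphere macromolecular crowders in a
    periodic box, low-friction Langevin dynamics with temperature replica
    exchange, and the ensemble statistics used to characterise the apo and
    calcium-saturated conformational ensembles: overlap/asphericity free
    energy landscapes via the weighted histogram analysis method, helicity,
    EF-hand interhelical angles, and contact probability/covariance
    matrices.  Also implements circular-dichroism thermal-denaturation
    analysis: mean-residue-ellipticity conversion, two- and three-state
    unfolding models built on the modified Gibbs-Helmholtz equation,
    nonlinear least-squares fitting and synthetic melting-curve generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tibble,
    withr,
    yaml
Config/testthat/edition: 3
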