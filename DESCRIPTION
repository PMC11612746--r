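Package: nemapoly
Title: Hybrid Nematic-MPCD and Molecular Dynamics Simulation of Polymers in Nematic Solvents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a single flexible bead-spring polymer two-way coupled to a
    nematic liquid-crystal solvent, using a hybrid of nematic multi-particle
    collision dynamics (N-MPCD) for the solvent and velocity-Verlet molecular
    dynamics for the FENE chain. Includes cylindrical confinement with planar
    anchoring and perfect-slip walls, conformation analysis (gyration tensor,
    end-to-end scaling, tangent statistics), hairpin defect detection, tracking
    and counting statistics, anisotropic diffusion measurement, and the matching
    analytic models (single-segment partition function, Perrin ellipsoid drag
    with wall correction, Kramers hopping of hairpins along the backbone).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
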