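Package: sclamella
Title: Coarse-Grained Models and Structural Analysis of Stratum Corneum
    Lipid Lamellae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing coarse-grained (CG) models of
    stratum corneum lipids (ceramides NS/NP/AS/AP, cholesterol, free fatty
    acids, water). Provides CG bead mappings and molecule templates with
    mass-conserving atom-to-bead assignment, forward mapping of atomistic
    frames to CG frames, Boltzmann inversion of Gaussian bond-length and
    bond-angle distributions into harmonic force constants, a lamellar
    structural-metric suite (area per lipid, normalized lipid area,
    peak-to-peak thickness, inertia-tensor tilt, nematic order,
    density-overlap interdigitation, extended-conformation fraction, water
    per lipid), schedule arithmetic for shape-annealing self-assembly
    protocols, and synthetic gel-phase bilayer/multilayer generators with
    known ground truth for validating every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
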