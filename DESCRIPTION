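Package: helixforce
Title: Coarse-Grained Alpha-Helix Models and Static Electrostatic Forces
    in Helix Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits coarse-grained cylinder-and-spheres models of alpha-helices
    from PDB coordinates (principal-axis fit by singular value decomposition,
    mean backbone radius, per-residue sidechain spheres), attaches robotic-style
    local coordinate frames composed as homogeneous transforms, and estimates
    the net static electrostatic interaction force within alpha-helix bundles
    via Coulomb's law with integer sidechain charges at physiological pH.
    Includes an ideal-helix generator for fully synthetic end-to-end runs and
    diagnostics that quantify the straight-axis and sidechain-sphere
    approximations (radial-distance profiles, skew-angle regression,
    pooled sidechain shape statistics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
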