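Package: actinkinetics
Title: Actin Assembly Kinetics Under Macromolecular Crowding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of actin filament assembly kinetics in
    crowded solutions. Provides mean-square-displacement and diffusion-
    coefficient estimation for actin monomers diffusing near filament barbed
    ends, filament-monomer inter-distance analysis, screened-Coulomb polar
    solvation free-energy combination for point-charge systems, elongation-
    rate extraction from TIRF-style timelapse stacks with kymograph
    construction and one-way ANOVA/Tukey condition comparison, pyrene
    polymerization-curve half-maximum slope rate statistics, and crowding-
    agent concentration arithmetic. Seeded synthetic-data generators emulate
    Brownian monomer trajectories, growing-filament timelapses, and sigmoidal
    pyrene fluorescence curves for validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
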