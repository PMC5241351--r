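Package: mesomix
Title: Mesoscopic Structure Analysis of Binary Alcohol/Water Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of mesoscale segregation and hydrogen bonding in binary
    alcohol/water mixtures, together with pressure perturbation calorimetry
    (PPC) data reduction. Provides a geometric hydrogen-bond detector with
    minimum-image periodic boundary handling and alcohol-centric bond
    classification; a sub-box occupancy non-ideality statistic compared
    against a matched random-mixture null ensemble; thermogram spike
    integration, heat-capacity pressure-derivative window gradients and
    deviation-from-linear-mixing arithmetic; the thermal-expansivity and
    hydration-layer heat models as forward/inverse calculations; readers and
    writers for XYZ, PDB, DL_POLY HISTORY and thermogram CSV files; and a
    synthetic-data generator that plants known hydrogen bonds, clustering
    levels and pulse areas so every analysis stage is testable without
    molecular dynamics runs or instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    pracma,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
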