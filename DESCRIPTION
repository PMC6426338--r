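Package: forestclim
Title: Window-Paired Analysis of Forest-Cover Effects on Local Land-Surface Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how decadal forest-cover change drives local
    land-surface temperature (LST) through albedo and evapotranspiration (ET).
    Implements a moving-window focal/reference cell-pairing strategy for gridded
    change layers, generalized least squares and paired mixed models with
    parametric spatial correlation structures selected by AICc, piecewise
    structural equation modeling with d-separation tests (Fisher's C) and
    direct/indirect/total effect decomposition, and scenario-based projection of
    LST change from forest-change rasters. Includes a seeded synthetic-landscape
    generator with known causal structure for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
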