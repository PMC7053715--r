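Package: cropshock
Title: Crop Diversification and Farm Robustness Under Labor Shocks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A deterministic farm- and regional-scale bioeconomic simulator for
    studying whether crop diversification makes farming units more robust to
    seasonal labor shortages. Farming units allocate crops to plots by an exact
    constrained integer program, harvest under a labor budget by optimal
    (possibly partial) labor allocation, and interact through an endogenous
    constant-elasticity market price driven by the region's aggregate harvest.
    Includes a Florida strawberry/tomato case parameterization, a synthetic
    region generator for property testing, shock-sweep experiment drivers over
    intensity, duration and regional strategy composition, and robustness
    metrics (mean funds by strategy, diversification advantage fractions and
    crossover intensities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
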