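Package: grasslandRTR
Title: Removal N-Mixture Density Models and Spatial Randomization Tests for
    Grassland Conservation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the placement of grassland-bird conservation
    area networks against spatially explicit population density predictions.
    Simulates spatially autocorrelated land-cover mosaics, climate surfaces,
    nested conservation-area networks and removal-protocol point-count
    surveys with known parameters; fits removal multinomial-Poisson N-mixture
    models by maximum likelihood with parametric-bootstrap goodness-of-fit
    and overdispersion correction; predicts 1-km2 density surfaces with
    coefficient-shift error propagation; and tests conservation-area
    representation with a constrained random translation-rotation (RTR)
    spatial null model, minimum-set optimal planning, and
    percent-of-population coverage summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
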