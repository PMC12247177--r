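Package: ancspatial
Title: Spatial Disparity Analysis of Antenatal Care Utilization with
    Bayesian Geo-Additive Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing spatial disparities in areal health
    indicators such as the proportion of women receiving the recommended
    number of antenatal care (ANC) contacts. Provides sample-size-weighted
    aggregation of regional count data, spatial neighbourhood graphs
    (queen contiguity, k-nearest neighbours, distance bands) with binary or
    row-standardised weight matrices, global Moran's I and Geary's C tests
    with analytic and permutation inference, a rank-based normalizing
    transform, a Bayesian geo-additive Gaussian model with
    Besag-York-Mollie (intrinsic CAR plus i.i.d.) spatial random effects and
    second-order random-walk covariate smooths fitted by a conjugate Gibbs
    sampler, model comparison via DIC, WAIC and the conditional predictive
    ordinate, probability-integral-transform calibration checks, and a
    synthetic areal-data generator for lattice simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    ape,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
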