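Package: monkeyhab
Title: Village-Development-Aware Habitat Quality Modelling for the Yunnan
    Snub-Nosed Monkey
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for assessing how rural village development
    degrades habitat quality of the Yunnan snub-nosed monkey (Rhinopithecus
    bieti) in northwest Yunnan. Scores village socio-economic development from
    30 indicators by a PCA-weighted composite and assigns seven ordinal grades;
    scores forest survey plots by a weighted ecological quality index; computes
    distance-decayed threat degradation and half-saturation habitat quality
    over a categorical land-cover raster from graded villages, rural roads and
    land-derived threats; and interprets the result with global Moran's I,
    Getis-Ord Gi* hot-spot classification, quartic kernel density and zonal
    statistics over monkey group ranges. Includes a synthetic landscape
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
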