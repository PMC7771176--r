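Package: volewatch
Title: Predator Numerical Responses to Grassland Vole Cycles from Roadside Counts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of long-term predator and hare
    monitoring on a fixed roadside-count itinerary in cyclic grassland vole
    landscapes. Builds kilometric abundance indices (KAI) from multi-night
    count sessions, interval-transect and communal-score prey indices with
    bootstrap uncertainty, a composite grassland prey-resource index, maximum
    likelihood hazard-rate detection functions with truncation selection and
    AIC covariate comparison for line-transect density estimation, allometric
    theoretical daily food intake (TFI) aggregation into community tables,
    Poisson numerical-response models with permutation inference, Monte-Carlo
    habitat randomization tests, and a synthetic-data generator with known
    ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    xml2,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
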