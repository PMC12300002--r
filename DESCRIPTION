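Package: herdtk
Title: Dynamic Exposure and Population Toxicokinetics of PFAS in Beef Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates lifetime exposure of beef cattle to perfluoroalkyl
    substances (PFOS, PFDA) on farms with biosolids-contaminated soils, and
    predicts serum, muscle, and milk concentrations with a stochastic
    first-order one-compartment toxicokinetic model. Daily absorbed doses are
    assembled from stored feed (soil-to-plant transfer with first/second-cut
    adjustment and bale-weighted mixing), pasture forage, incidental soil
    ingestion, drinking water, and dam milk for nursing calves. Includes
    model-evaluation statistics against biomonitoring data (percentage error,
    MAPE, fold ratios, action-level exceedance, partition-coefficient
    meta-analysis), farm-management intervention simulations with a simple
    economic comparison, and a synthetic-farm generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
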