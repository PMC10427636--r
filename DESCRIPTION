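Package: physiodrought
Title: Disentangling Structural and Physiological Vegetation Responses to Drought
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isolates the physiological component of vegetation drought
    responses from gridded observation streams (relative solar-induced
    fluorescence, land-surface-temperature derived evapotranspiration, and
    the midday/midnight vegetation optical depth ratio). Provides a
    simplified surface energy balance model converting midday LST to daily
    latent heat flux, anomaly extraction (monthly climatology plus
    locally-weighted trend removal), soil-moisture drought detection over a
    40-year record, a two-model random-forest decomposition into structural
    (leaf-area driven) and physiological parts with multiple-linear-regression
    and Shapley-value variants, spatial driver attribution, and the
    composite and bootstrap statistics used to summarise drought
    trajectories. Ships a synthetic gridded ecohydrological data generator
    with known latent physiological signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
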