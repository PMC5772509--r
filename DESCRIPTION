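Package: deglaciso
Title: Atmospheric CO2 Effects on Carbon Isotope Records of C3 Plants and
    Fauna over the Last Deglaciation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward models of C3 photosynthetic carbon isotope
    fractionation (Farquhar-type diffusion/carboxylation models with
    constant or CO2-dependent ci/ca, and the hyperbolic
    discrimination model of Schubert and Jahren) driven by ice-core
    records of CO2 concentration and atmospheric d13C.  Builds
    continuous atmospheric curves from irregular ice-core samples by
    Monte Carlo average smoothing splines with a frequency cutoff,
    detects high-amplitude isotopic episodes, adjusts fossil collagen
    and cellulose d13C archives for geographic variability in mean
    annual precipitation, altitude and latitude, corrects for
    deglacial precipitation change using a multi-model climate
    ensemble, and decomposes the deglacial isotopic shift into pCO2
    and precipitation components with propagated uncertainties.
    Includes a synthetic-data generator with known ground truth for
    end-to-end validation, and RMSE/AIC/BIC model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
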