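# deglaciso

Quantifying the effect of atmospheric CO2 on the stable carbon isotope
composition of C3 plants and fauna across the last deglaciation.

## What this is for

The δ¹³C of C3 plant tissue — and of the herbivores that eat it — is
widely used to reconstruct past environments (precipitation, canopy
cover, C3/C4 balance). But δ¹³C also responds to the atmosphere itself:
both to the isotopic composition of CO2 and, under several models of
photosynthetic fractionation, to its *concentration*. Across the last
deglaciation pCO2 rose by ~80 ppmv, and ignoring that rise risks
misreading an atmospheric signal as an ecological one. `deglaciso` is for
isotope palaeoecologists and palaeoclimate modellers who want to compute,
propagate and subtract the pCO2 contribution from fossil δ¹³C archives.

The package implements:

* **Forward fractionation models.** The diffusion/carboxylation model
  `δ¹³Cp = δ¹³C_CO2 − a − (b − a)·ci/ca` (a = 4.4‰, b = 28.2‰) with a
  constant ci/ca = 0.6 ("Farquhar-1982") or ci/ca linear in ca
  (gymnosperm "Voelker-2016g": 0.00038·ca + 0.502; angiosperm
  "Voelker-2016a": 0.00031·ca + 0.649); and the hyperbolic model
  ("SJ-2012") `Δ¹³C = A·B·(pCO2+C) / (A + B·(pCO2+C))` with A = 28.26,
  B = 0.22, C = 23.9, converted through the exact
  `Δ = (δ_CO2 − δp)/(1 + δp/1000)` inversion.
* **Monte Carlo average splines** (`mca_spline`) turning irregular
  ice-core CO2 / δ¹³C_CO2 samples into continuous curves with 1σ
  envelopes (1000 error-perturbed cubic-spline replicates, 375-yr cutoff
  period), an anthropogenic-era splice, forward-modelled plant-δ¹³C
  curves with propagated and expanded uncertainties, and detection of
  high-amplitude episodes (>1‰ at >0.25‰/kyr).
* **Geographic adjustment** of fossil records to a reference environment
  (MAP 1000 mm, 840 m, 50°) via the modern MAP/altitude/latitude
  regressions, with nearest-cell grid lookup for site covariates.
* **Record curation** (C3-dominant sites, lichen-feeder and
  industrial-era exclusion) and tissue conversions (collagen −5.1‰,
  cellulose −1.0‰ to the bulk-leaf scale).
* **Climate-ensemble precipitation correction**: per-site and cohort
  Δ(δ¹³C_MAP) from multi-model LGM / mid-Holocene MAP, with inter-model
  spread.
* **Decomposition** of the adjusted deglacial shift,
  `Δδ_adj ≈ Δδ_pCO2 + Δδ_MAP + Δδ_CO2`, with quadrature error
  propagation, per-100-ppmv scaling (rise 80.5 ppmv) and a one-sided
  Welch shift test.
* **Model comparison** by RMSE and Gaussian AIC/BIC, and a
  **synthetic-data generator** producing every pipeline input with known
  ground truth.

## Worked example

```r
library(deglaciso)

## deglacial change predicted by the hyperbolic model, 190 -> 270 ppmv
sj <- fractionation_model("sj2012")
diff(predict_delta_p(sj, pco2 = c(190, 270), d13c_co2 = -6.5))
#> [1] -1.922948

## full synthetic-scenario analysis
sc  <- sim_scenario(scenario_config(seed = 42))
rec <- adjust_records(sc$records)
analyze_cohorts(rec, sc$gcm)
#> == Deglacial d13C analysis ==
#>  window   n      mean       sd        se
#>     pre 200 -19.93679 2.276788 0.1609932
#>    post 200 -22.75745 2.306942 0.1631255
#> shift test (post < pre): t = -12.3, p = 5.1e-30
#> <map_effect> -0.581 +/- 0.0934 per mil (inter-model 1-sigma, 7 models; 100% of records at sites predicted wetter)
#> <effect_decomposition> (per mil, Holocene minus pre-glacial)
#>   adjusted shift   : -2.82 +/- 0.229
#>   MAP contribution : -0.581 +/- 0.0934
#>   pCO2 residual    : -2.24 +/- 0.247
#>   per 100 ppmv     : -2.78 +/- 0.307  (rise 80.5 ppmv)
```

Reading the output: the geographically adjusted record means drop by
2.82‰ from the pre-glacial (>20 kyr BP) to the Holocene (<10 kyr BP)
window; the climate ensemble attributes −0.58‰ of that to wetter Holocene
conditions; the residual −2.24‰ is the pCO2 effect, here −2.78‰ per
100 ppmv — close to the scenario's generating model (SJ-2012 implies
about −2.4‰ per 100 ppmv at these concentrations, plus the small
source-air term left uncorrected in this call).

Ice-core curve building works the same way from sample tables:

```r
cv <- mca_spline(sc$icecore$pco2, cutoff_yr = 375, n_rep = 1000, seed = 42)
cv
#> <spline_curve> 401 points, 0-40 kyr BP (step 0.1 kyr)
#>   cutoff 375 yr, 1000 replicates, perturb = gaussian, seed = 42
#>   age     mean    sigma
#> 1 0.0 271.2777 1.560090
#> ...
```

Pairing a CO2 curve with a δ¹³C_CO2 curve on the same grid gives model
plant-δ¹³C curves (`model_curve()`) and their high-amplitude episodes
(`detect_episodes()`).

CSV-based compilations (records plus a `model, site_id, map_lgm_mm,
map_midh_mm` ensemble table) run through
`analyze_compilation(records_file, gcm_file)`.

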