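---
title: "Quantifying the pCO2 effect on C3 plant and faunal d13C over the last deglaciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the pCO2 effect on C3 plant and faunal d13C over the last deglaciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deglaciso)
```

## The problem

The stable carbon isotope composition of C3 plant tissue
($\delta^{13}\mathrm{C_p}$, per mil VPDB) is set by the composition of the
CO2 the plant assimilates and by the physiological fractionation between
atmosphere and tissue. Fossil archives of plant carbon — wood cellulose,
and herbivore bone collagen one trophic step removed — are routinely read
as records of local environment (precipitation, canopy cover). But over
the last deglaciation atmospheric CO2 rose by roughly 80 ppmv while its
own isotopic composition barely moved, and several models of
photosynthetic fractionation predict that this rise alone depresses
$\delta^{13}\mathrm{C_p}$ by 1–2 per mil. `deglaciso` implements the full
chain needed to quantify that effect: forward fractionation models driven
by ice-core curves, geographic normalisation of scattered fossil records,
a climate-model-ensemble correction for precipitation change through time,
and the final decomposition of the observed isotopic shift.

## Fractionation models

Four forward models are provided through `fractionation_model()`.

The Farquhar-family models apply the linear-in-$\delta$
diffusion/carboxylation expression

$$\delta^{13}\mathrm{C_p} = \delta^{13}\mathrm{C}_{CO_2} - a - (b - a)\,
\frac{c_i}{c_a},$$

with diffusion fractionation $a = 4.4$ per mil and net carboxylation
discrimination $b = 28.2$ per mil. They differ in the leaf gas-exchange
strategy:

* **Farquhar-1982** — constant $c_i/c_a = 0.6$. At fixed source
  $\delta^{13}\mathrm{C}_{CO_2}$ it is independent of pCO2; the ratio is
  chosen because it reproduces the modern global-mean plant value of about
  $-27.1$ per mil at a modern source composition of $-8.4$ per mil.
* **Voelker-2016g** — gymnosperm strategy,
  $c_i/c_a = 0.00038\,c_a + 0.502$.
* **Voelker-2016a** — woody-angiosperm strategy,
  $c_i/c_a = 0.00031\,c_a + 0.649$.

The fourth, **SJ-2012**, is the hyperbolic discrimination model fitted to
growth-chamber and glacial fossil data,

$$\Delta^{13}\mathrm{C} = \frac{A\,B\,(\mathrm{pCO_2} + C)}
{A + B\,(\mathrm{pCO_2} + C)},\qquad A = 28.26,\; B = 0.22,\; C = 23.9,$$

converted to $\delta^{13}\mathrm{C_p}$ through the exact definition
$\Delta^{13}\mathrm{C} = (\delta_{CO_2} - \delta_p)/(1 + \delta_p/1000)$.
Two conventions are deliberate and worth stating. The Farquhar expression
is applied as the linear-in-$\delta$ approximation (its standard printed
form); the hyperbolic model uses the exact
$\Delta\!\leftrightarrow\!\delta$ inversion, because its constants were
fitted on the $\Delta$ scale. A consequence of the exact inversion is that
a shift $s$ in source $\delta^{13}\mathrm{C}_{CO_2}$ moves the SJ-2012
plant value by $s/(1 + \Delta/1000)$ — about 2% less than $s$ — whereas
the Farquhar family passes it through exactly.

Linear $c_i/c_a$ strategies are clamped to the open interval $(0,1)$ with
a warning: the calibrations were never evaluated outside the 150–4200 ppmv
range, and a ratio outside $(0,1)$ is unphysical for extreme synthetic
input. Per-model parameter counts used for information criteria are
$k = 3$ for the constant-ratio and hyperbolic models ($a, b, r$ and
$A, B, C$) and $k = 4$ for the linear-strategy models; the sources do not
state the convention they scored with, so `k` is carried on the model
object and reported alongside every score.

```{r models}
sj <- fractionation_model("sj2012")
# deglacial 190 -> 270 ppmv change at fixed source composition
diff(predict_delta_p(sj, pco2 = c(190, 270), d13c_co2 = -6.5))
```

## Atmospheric curves from ice-core samples

`mca_spline()` turns irregular, individually uncertain ice-core samples
into a continuous curve with a pointwise 1-sigma envelope: each of
`n_rep = 1000` replicates perturbs every sample within its stated error
and fits a cubic smoothing spline; the curve is the pointwise mean and
standard deviation of the replicates, on a default 0.1 kyr grid confined
to the data span (no extrapolation).

Numerical choices:

* **Cutoff period.** The smoothing strength is expressed as a cutoff
  period (default 375 yr). The spline's stiffness is set so that its
  amplitude response is 50% at that period — in the continuous limit a
  smoothing spline acts as a low-pass filter with response
  $1/(1 + (\mu/\rho)(2\pi f)^4)$, giving
  $\mu = \rho\,(P_c/2\pi)^4$ for point density $\rho$. The mapping was
  verified on sinusoids (response 0.50 at $P_c$, 0.14 at $P_c/2$, 0.98 at
  $2.7 P_c$). An explicit `lambda` overrides the mapping.
* **Perturbation distribution.** "Within the 1-sigma range" is read as
  Gaussian with sd equal to the stated sigma; a `perturb = "uniform"`
  option draws uniformly on $\pm 1\sigma$ instead. The choice is recorded
  in the curve's metadata.
* **Outliers** flagged in the input are excluded before fitting; with all
  sigmas zero and one replicate the procedure reduces to a single
  smoothing-spline fit, and reproduces data in the penalty's null space
  (constants and lines) exactly.
* **Anthropogenic merge.** Industrial-era records are splined *without* a
  cutoff (the rapid rise is signal), and spliced in front of the
  pre-industrial curve with the modern fit taking precedence from its
  oldest sample onward and a linear cross-fade over one grid step at the
  junction. A gap wider than one grid step is an error rather than an
  invisible interpolation.

`model_curve()` pushes a pair of atmospheric curves through a
fractionation model: the mean is the model at the curve means, and the
uncertainty is Monte-Carlo propagated by drawing the two inputs
independently from their pointwise errors. `expanded_uncertainty()`
combines a propagated curve sigma in quadrature with the 1.62 per mil
spread of the modern plant distribution, giving the conservative envelope
appropriate when a curve is read as "the plausible range of C3 plants".

`detect_episodes()` flags maximal intervals where the curve moves faster
than 0.25 per mil/kyr (centred differences) and by more than 1 per mil in
total, excluding ages younger than 0.2 kyr BP (the anthropogenic signal is
two orders of magnitude faster and would otherwise dominate).

## Geographic adjustment and record curation

Fossil records are moved to a common reference environment
(MAP = 1000 mm/yr, altitude = 840 m, latitude = 50°) with the modern
regression terms

$$\delta_{MAP} = 5.6\,[\log_{10}(MAP+300) - \log_{10}(1300)],\quad
\delta_{alt} = 0.00019\,(840 - alt),\quad
\delta_{lat} = 0.0124\,(|lat| - 50),$$

added to the measured value (`geo_adjust()`). The adjustment is exactly
invertible — it normalises geography without destroying information — and
on synthetic cohorts generated with the same regressions plus scatter it
removes the dependence on all three covariates (regression slopes
indistinguishable from zero afterwards).

Site altitude and modern MAP may be supplied directly or looked up from
gridded fields. The lookup (`grid_lookup()`) is nearest-cell, not
interpolated: it is reproducible, resolution-appropriate, and errors
loudly on out-of-bounds sites or missing-data cells. Grids are plain
in-memory lat/lon matrices (`climate_grid()`, long-format CSV reader
included), keeping the pipeline free of binary raster dependencies.

Curation (`filter_records()`) applies the compilation rules: sites with
at least 90% C3 vegetation, exclusion of lichen-consuming taxa (lichens
are not C3 vascular plants), an optional age window, and exclusion of the
industrial era. "Industrial" is fixed at ages younger than 0.2 kyr BP
(about 1750 CE) — the sources say only "exclude the industrial era", so
the cutoff is explicit and configurable. Filters are idempotent and
order-independent, and removal counts are reported.

Tissue conversions place both archives on the bulk-leaf (diet) scale:
collagen minus the 5.1 per mil collagen–diet enrichment, cellulose minus
the ~1 per mil cellulose–leaf offset. The offset's sign (leaf = cellulose
− 1) is fixed by consistency: Holocene collagen − 5.1 and cellulose − 1
must agree on the same diet, and on co-generated synthetic cohorts the raw
archives differ by 5.1 − 1.0 = 4.1 per mil as expected.

## Precipitation correction and decomposition

The deglacial comparison contrasts records older than 20 kyr BP with
records younger than 10 kyr BP (industrial era excluded). The geographic
adjustment removes *spatial* bias only; precipitation also changed *in
time*, and that component is constrained from a seven-member coupled
climate-model ensemble of MAP at the LGM (21 kyr) and mid-Holocene
(6 kyr):

$$\Delta(\delta^{13}\mathrm{C}_{MAP}) =
-5.6\,[\log_{10}(MAP_{midH}+300) - \log_{10}(MAP_{LGM}+300)].$$

The sign convention is fixed by the physics: the value is the MAP
contribution to the (Holocene − pre-glacial) difference and is *negative*
where the Holocene is wetter. (The formula has appeared in print with the
two epochs transposed; the implementation follows the stated direction of
the effect, and the antisymmetry under swapping the epochs is tested.)

`cohort_map_effect()` aggregates per-site, per-model effects to the
cohort: each ensemble member yields one cohort value (sites weighted by
their record counts, so duplicated table rows change nothing; equal-site
weighting is available by flag), and the reported mean and sigma are the
across-member mean and spread. The record-weighted fraction of sites each
member predicts wetter is reported alongside.

`decompose_shift()` then closes the budget,

$$\Delta\bar\delta_{adj} \approx \Delta\bar\delta_{pCO_2} +
\Delta\bar\delta_{MAP} + \Delta\bar\delta_{CO_2},$$

solving for the pCO2 residual and propagating the component 1-sigmas in
quadrature. The source-air term $\Delta\bar\delta_{CO_2}$ is about
0.05 per mil between the two windows and is dropped by default, exactly as
the budget is normally applied; passing `delta_co2iso = 0.05` retains it
and changes nothing by more than that amount. The residual is rescaled to
per-100-ppmv units with the deglacial rise of 80.5 ppmv. The uncertainty
on the adjusted shift is the standard error of the difference of group
means (the sources do not state their construction; this is the standard
choice). Group separation is tested with a one-sided Welch two-sample
t-test of Holocene against pre-glacial values: there is no natural pairing
between two cohorts of different ages, so a paired test is not meaningful,
and published paired-test statistics may not be exactly reproducible under
this reading.

## Model comparison

`score_models()` evaluates each fractionation model's curve at the record
ages (linear interpolation between grid points), and scores the residuals
by RMSE and by Gaussian AIC/BIC with the error variance at its
maximum-likelihood value, $\hat\sigma^2 = \overline{r^2}$, so
$\log\mathcal{L} = -\tfrac{n}{2}(\log 2\pi + \log\hat\sigma^2 + 1)$. A
fixed error scale can be imposed instead (`sigma =`), which penalises
absolute misfit rather than letting each model set its own variance.
Records outside the curve span are skipped with a message, never
extrapolated.

Scoring compares records to *atmosphere-only* predictions. If the records
also carry an uncorrected temporal precipitation signal, the best-fitting
curve is legitimately not the generating model — the statistic is honest
about total misfit. The package's model-selection validation therefore
runs on scenarios without temporal MAP change; with the confounder
enabled the ranking measures the confounder, which is a property of the
data, not of the scorer.

## The synthetic-data generator

`sim_scenario()` generates every input the pipeline consumes, with ground
truth stored for recovery tests. Its defaults are the deglacial study
conditions: a logistic CO2 ramp from a 190 ppmv glacial to a 270 ppmv
Holocene plateau centred at 14 kyr BP (logistic rather than piecewise
linear, so episode detection has a differentiable truth); source
$\delta^{13}\mathrm{C}_{CO_2}$ of $-6.5$ per mil with fluctuations up to
0.3 per mil on an 8 kyr period; measurement noise of 2 ppmv and 0.08 per
mil; 40 sites scattered over 40–70° latitude with modern MAP 300–1500
mm/yr; a 30% drier LGM; a seven-member pseudo-ensemble with 15% lognormal
inter-model spread; 400 records split evenly between collagen and
cellulose across the two comparison windows, with 1 per mil record noise
(the scatter scale of faunal compilations). All randomness flows from one
master seed through named sub-streams, so any stage can be regenerated
independently and reproducibly.

Each record is assembled as model prediction + geographic deviation (with
MAP at the *time of growth*: LGM precipitation for old records) + tissue
offset + noise, and the generator stores the injected window-mean shifts
(`pco2_shift`, `co2iso_shift`, `map_shift`, effective `rise_ppmv`).

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: age-model and radiocarbon-calibration
uncertainty (ages are taken as exact), canopy effects, species-level diet
selectivity, temporal clustering of samples, inter-laboratory offsets,
spatially correlated climate fields, and any bias in the climate-model
ensemble itself. Recovery results on synthetic scenarios validate the
arithmetic and the statistical machinery, not those field realities.

## Validation scale and determinism

The shipped validation runs at desk scale, chosen to exercise every code
path at meaningful statistical power: spline envelopes at 150–1000
replicates on 60–240 samples; end-to-end parameter recovery over 50
seeded scenarios of 400 records (bias on the per-100-ppmv effect bounded
at 0.1 per mil); model selection over 20 seeded scenarios at 0.5 per mil
record noise (generating model ranked first at least 80% of the time).
The recovery comparison supplies the generator's known source-air term to
the decomposition, mirroring how the term is evaluated from ice-core
curves and then dropped as negligible in practice.

## Worked analysis

```{r pipeline}
sc <- sim_scenario(scenario_config(seed = 42))
rec <- adjust_records(sc$records)
analyze_cohorts(rec, sc$gcm)
```

The same analysis runs from deposited-style CSV tables through
`analyze_compilation(records_file, gcm_file)`, which curates, adjusts and
decomposes in one call.

## Known limitations

* The Farquhar expression omits mesophyll conductance, photorespiration
  and dark respiration; those terms scale with $1/c_a$ and are assumed
  negligible here, an assumption that matters most at glacial CO2 levels.
* The cutoff-period mapping is a frequency-domain idealisation; for very
  uneven sampling the effective attenuation varies with local point
  density.
* Cohort MAP aggregation offers record- and site-weighting only; the
  published compilations do not state their convention, so small
  differences against published cohort values are expected.
* AIC/BIC values depend on the assumed per-model parameter counts and the
  Gaussian MLE error model; published information-criterion values
  computed under unstated conventions may differ by a constant.
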