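#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: a deglacial
#' ice-core ramp with measurement noise, geographically scattered sites,
#' proxy records produced by a chosen fractionation model plus geographic
#' and tissue offsets, and a seven-member pseudo climate-model ensemble.
#' Defaults follow the deglacial setting: an 80 ppmv CO2 rise from a
#' 190 ppmv glacial to a 270 ppmv Holocene plateau, atmospheric d13C_CO2
#' around -6.5 per mil with fluctuations up to 0.3 per mil, Eurasian-style
#' site scatter, a 30% drier LGM, and record noise of 1 per mil (the
#' scatter scale of faunal compilations).
#'
#' @param seed master seed; every stage draws from a named sub-stream of it.
#' @param age_max ice-core span, kyr BP (records must lie inside).
#' @param n_pco2,n_d13c ice-core sample counts for the two series.
#' @param pco2_glacial,pco2_holocene plateau concentrations, ppmv.
#' @param ramp_mid,ramp_width centre (kyr BP) and logistic width (kyr) of
#'   the deglacial ramp.
#' @param pco2_noise,d13c_noise 1-sigma measurement errors (ppmv, per mil).
#' @param d13c_baseline,d13c_fluct,d13c_period atmospheric d13C_CO2
#'   baseline (per mil), peak-to-peak fluctuation amplitude (per mil) and
#'   fluctuation period (kyr).
#' @param model the true fractionation model (name or
#'   [fractionation_model()]).
#' @param n_sites,lat_range,lon_range,alt_range,map_range site count and
#'   uniform ranges for latitude, longitude (degrees), altitude (m) and
#'   modern MAP (mm/yr).
#' @param lgm_multiplier,midh_multiplier true MAP at the LGM / mid-Holocene
#'   as multiples of modern MAP (default 0.7 / 1.0: a drier glacial).
#' @param gcm_spread,n_gcm inter-model lognormal sigma and ensemble size.
#' @param n_records,collagen_fraction record count and archive mix.
#' @param pre_window,post_window age windows (kyr BP) the records are drawn
#'   from, uniformly.
#' @param map_transition_age age (kyr BP) above which a record grew under
#'   LGM precipitation (below: mid-Holocene/modern).
#' @param record_noise 1-sigma analytical + ecological noise on record
#'   d13C, per mil.
#' @param eps_diet,cellulose_offset tissue offsets, per mil.
#' @return list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1,
                            age_max = 40, n_pco2 = 240, n_d13c = 160,
                            pco2_glacial = 190, pco2_holocene = 270,
                            ramp_mid = 14, ramp_width = 1.5,
                            pco2_noise = 2, d13c_noise = 0.08,
                            d13c_baseline = -6.5, d13c_fluct = 0.3,
                            d13c_period = 8,
                            model = "SJ-2012",
                            n_sites = 40,
                            lat_range = c(40, 70), lon_range = c(-10, 60),
                            alt_range = c(0, 1500), map_range = c(300, 1500),
                            lgm_multiplier = 0.7, midh_multiplier = 1.0,
                            gcm_spread = 0.15, n_gcm = 7,
                            n_records = 400, collagen_fraction = 0.5,
                            pre_window = c(20.5, 32),
                            post_window = c(0.3, 9.5),
                            map_transition_age = 15,
                            record_noise = 1.0,
                            eps_diet = 5.1, cellulose_offset = 1.0) {
  cfg <- as.list(environment())
  stopifnot(cfg$pco2_glacial > 0, cfg$pco2_holocene > 0,
            cfg$pco2_noise >= 0, cfg$d13c_noise >= 0,
            cfg$record_noise >= 0, cfg$gcm_spread >= 0,
            cfg$n_records >= 1, cfg$n_sites >= 1, cfg$n_gcm >= 2)
  if (is.character(cfg$model)) cfg$model <- fractionation_model(cfg$model)
  structure(cfg, class = "scenario_config")
}

# ground-truth atmospheric histories implied by a scenario
truth_functions <- function(cfg) {
  list(
    pco2 = function(age)
      cfg$pco2_holocene + (cfg$pco2_glacial - cfg$pco2_holocene) *
        stats::plogis((age - cfg$ramp_mid) / cfg$ramp_width),
    d13c = function(age)
      cfg$d13c_baseline +
        (cfg$d13c_fluct / 2) * sin(2 * pi * age / cfg$d13c_period)
  )
}

#' Generate synthetic ice-core sample series
#'
#' Draws irregularly spaced sample ages over the scenario span and
#' evaluates the true atmospheric histories (a logistic deglacial CO2 ramp;
#' a slowly fluctuating d13C_CO2) plus Gaussian measurement noise at each
#' sample's stated 1-sigma.
#'
#' @param cfg a [scenario_config()].
#' @return list with data frames `pco2` and `d13c` (columns `age`, `value`,
#'   `sigma`, `core`, `outlier`) and `truth` (the noise-free functions of
#'   age).
#' @export
sim_icecore <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  tr <- truth_functions(cfg)
  mk <- function(n, fn, sig, stream) with_seed(stream_seed(cfg$seed, stream), {
    age <- sort(c(0, cfg$age_max, runif(n - 2L, 0, cfg$age_max)))
    data.frame(age = age, value = fn(age) + rnorm(n, 0, sig),
               sigma = sig, core = "SYN", outlier = FALSE)
  })
  list(pco2 = mk(cfg$n_pco2, tr$pco2, cfg$pco2_noise, "icecore_pco2"),
       d13c = mk(cfg$n_d13c, tr$d13c, cfg$d13c_noise, "icecore_d13c"),
       truth = tr)
}

#' Generate synthetic site locations
#'
#' Sites are drawn uniformly from the configured latitude, longitude,
#' altitude and modern-MAP ranges.
#'
#' @param cfg a [scenario_config()].
#' @return data frame with `site_id`, `lat`, `lon`, `altitude_m`, `map_mm`.
#' @export
sim_sites <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(stream_seed(cfg$seed, "sites"), {
    n <- cfg$n_sites
    data.frame(site_id = sprintf("S%03d", seq_len(n)),
               lat = runif(n, cfg$lat_range[1], cfg$lat_range[2]),
               lon = runif(n, cfg$lon_range[1], cfg$lon_range[2]),
               altitude_m = runif(n, cfg$alt_range[1], cfg$alt_range[2]),
               map_mm = runif(n, cfg$map_range[1], cfg$map_range[2]))
  })
}

#' Synthetic elevation and precipitation grids consistent with sites
#'
#' Builds smooth synthetic elevation and modern-MAP fields over the
#' scenario's geographic window and re-derives each site's `altitude_m` and
#' `map_mm` by nearest-cell lookup, so direct site values and
#' [grid_lookup()] agree exactly by construction.
#'
#' @param cfg a [scenario_config()].
#' @param resolution cell size in degrees (default 0.5).
#' @return list with `dem` and `clim` ([climate_grid()]s) and `sites` (as
#'   [sim_sites()], with grid-derived `altitude_m`, `map_mm`).
#' @export
sim_climate_grids <- function(cfg, resolution = 0.5) {
  sites <- sim_sites(cfg)
  la <- seq(cfg$lat_range[1] - 1, cfg$lat_range[2] + 1, by = resolution)
  lo <- seq(cfg$lon_range[1] - 1, cfg$lon_range[2] + 1, by = resolution)
  alt_field <- function(lat, lon)
    mean(cfg$alt_range) + diff(cfg$alt_range) / 2 *
      sin(lat / 7) * cos(lon / 11)
  map_field <- function(lat, lon)
    mean(cfg$map_range) + diff(cfg$map_range) / 2 *
      cos(lat / 9) * sin(lon / 13)
  dem <- climate_grid(la, lo, outer(la, lo, Vectorize(alt_field)))
  clim <- climate_grid(la, lo, outer(la, lo, Vectorize(map_field)))
  sites$altitude_m <- grid_lookup(dem, sites$lat, sites$lon)
  sites$map_mm <- grid_lookup(clim, sites$lat, sites$lon)
  list(dem = dem, clim = clim, sites = sites)
}

#' Generate synthetic proxy records with known ground truth
#'
#' Each record's d13C is assembled from the true fractionation model
#' evaluated at the atmospheric state for its age, the geographic
#' deviations implied by the MAP/altitude/latitude regressions (with MAP at
#' the *time of growth*: LGM precipitation for old records, modern for
#' Holocene ones), the archive tissue offset (collagen +5.1, cellulose
#' +1.0 relative to bulk leaf), and Gaussian noise. The decomposition of
#' the injected deglacial shift into pCO2, d13C_CO2 and MAP components is
#' stored in the `"truth"` attribute for parameter-recovery tests.
#'
#' @param cfg a [scenario_config()].
#' @param icecore output of [sim_icecore()] (for the truth functions);
#'   defaults to regenerating it from `cfg`.
#' @param sites output of [sim_sites()]; defaults to regenerating.
#' @return data frame of records (`id`, `archive`, `taxon_group`, `age`,
#'   `age_sigma`, `d13c`, `site_id`, `lat`, `lon`, `altitude_m`, `map_mm`,
#'   `c3_fraction`, `lichen_feeder`) with attribute `"truth"`: a list with
#'   the window-mean shifts `pco2_shift`, `co2iso_shift`, `map_shift`
#'   (per mil), the effective `rise_ppmv`, and `per100` (the injected pCO2
#'   effect per 100 ppmv).
#' @export
sim_records <- function(cfg, icecore = sim_icecore(cfg),
                        sites = sim_sites(cfg)) {
  stopifnot(inherits(cfg, "scenario_config"))
  tr <- icecore$truth
  with_seed(stream_seed(cfg$seed, "records"), {
    n <- cfg$n_records
    n_pre <- floor(n / 2); n_post <- n - n_pre
    age <- c(runif(n_pre, cfg$pre_window[1], cfg$pre_window[2]),
             runif(n_post, cfg$post_window[1], cfg$post_window[2]))
    si <- sample(nrow(sites), n, replace = TRUE)
    n_col <- round(cfg$collagen_fraction * n)
    archive <- sample(rep(c("collagen", "cellulose"),
                          c(n_col, n - n_col)))
    taxon <- ifelse(archive == "cellulose", "gymnosperm",
                    sample(c("Bos spp.", "Equus spp.", "Cervus spp."),
                           n, replace = TRUE))
    is_pre <- age > cfg$map_transition_age
    map_eff <- sites$map_mm[si] *
      ifelse(is_pre, cfg$lgm_multiplier, cfg$midh_multiplier)
    # atmospheric components of the truth
    pco2_comp <- predict_delta_p(cfg$model, tr$pco2(age), cfg$d13c_baseline)
    full <- predict_delta_p(cfg$model, tr$pco2(age), tr$d13c(age))
    co2iso_comp <- full - pco2_comp
    # geographic deviation: the negative of the adjustment terms, with the
    # time-of-growth MAP in place of the modern value
    geo_dev <- -(delta_map_term(map_eff) +
                 delta_alt_term(sites$altitude_m[si]) +
                 delta_lat_term(sites$lat[si]))
    tissue <- ifelse(archive == "collagen", cfg$eps_diet,
                     cfg$cellulose_offset)
    d13c <- full + geo_dev + tissue + rnorm(n, 0, cfg$record_noise)
    rec <- data.frame(id = sprintf("R%04d", seq_len(n)), archive = archive,
                      taxon_group = taxon, age = age, age_sigma = 0.1,
                      d13c = d13c, site_id = sites$site_id[si],
                      lat = sites$lat[si], lon = sites$lon[si],
                      altitude_m = sites$altitude_m[si],
                      map_mm = sites$map_mm[si],
                      c3_fraction = 1, lichen_feeder = FALSE)
    # injected deglacial shifts between the standard comparison windows
    pre <- age > 20; post <- age < 10
    wmean <- function(x, w) mean(x[w])
    map_resid <- delta_map_term(sites$map_mm[si]) - delta_map_term(map_eff)
    truth <- list(
      model = cfg$model$name,
      pco2_shift = wmean(pco2_comp, post) - wmean(pco2_comp, pre),
      co2iso_shift = wmean(co2iso_comp, post) - wmean(co2iso_comp, pre),
      map_shift = wmean(map_resid, post) - wmean(map_resid, pre),
      rise_ppmv = wmean(tr$pco2(age), post) - wmean(tr$pco2(age), pre))
    truth$per100 <- truth$pco2_shift * 100 / truth$rise_ppmv
    attr(rec, "truth") <- truth
    rec
  })
}

#' Generate a pseudo climate-model ensemble of palaeo-MAP
#'
#' Each ensemble member reports per-site LGM and mid-Holocene MAP equal to
#' the scenario truth (modern MAP times the epoch multiplier) perturbed by
#' member-specific multiplicative lognormal noise, emulating inter-model
#' spread.
#'
#' @param cfg a [scenario_config()].
#' @param sites output of [sim_sites()]; defaults to regenerating.
#' @return data frame with `model`, `site_id`, `map_lgm_mm`, `map_midh_mm`.
#' @export
sim_gcm_ensemble <- function(cfg, sites = sim_sites(cfg)) {
  stopifnot(inherits(cfg, "scenario_config"))
  with_seed(stream_seed(cfg$seed, "gcm"), {
    out <- lapply(seq_len(cfg$n_gcm), function(g) {
      n <- nrow(sites)
      data.frame(model = sprintf("GCM%02d", g), site_id = sites$site_id,
                 map_lgm_mm = sites$map_mm * cfg$lgm_multiplier *
                   exp(rnorm(n, 0, cfg$gcm_spread)),
                 map_midh_mm = sites$map_mm * cfg$midh_multiplier *
                   exp(rnorm(n, 0, cfg$gcm_spread)))
    })
    do.call(rbind, out)
  })
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running all four generators from one configuration.
#'
#' @param cfg a [scenario_config()] (or a seed, promoted via
#'   `scenario_config(seed = cfg)`).
#' @return list with `config`, `icecore`, `sites`, `records`, `gcm`.
#' @export
sim_scenario <- function(cfg = scenario_config()) {
  if (is.numeric(cfg)) cfg <- scenario_config(seed = cfg)
  ice <- sim_icecore(cfg)
  sites <- sim_sites(cfg)
  rec <- sim_records(cfg, ice, sites)
  gcm <- sim_gcm_ensemble(cfg, sites)
  list(config = cfg, icecore = ice, sites = sites, records = rec, gcm = gcm)
}
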