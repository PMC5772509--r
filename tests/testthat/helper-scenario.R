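# small scenario used across tests where the full default sizes are not
# needed; defaults otherwise identical to scenario_config()
quick_cfg <- function(seed = 1, ...) {
  scenario_config(seed = seed, n_pco2 = 80, n_d13c = 60, n_sites = 15,
                  n_records = 150, ...)
}

# a noise-free scenario with every site at the reference environment, so
# records fall exactly on the generating model curve after adjustment
reference_cfg <- function(seed = 1, ...) {
  scenario_config(seed = seed, n_pco2 = 60, n_d13c = 60, n_sites = 4,
                  n_records = 80, record_noise = 0,
                  pco2_noise = 0, d13c_noise = 0, d13c_fluct = 0,
                  lat_range = c(50, 50), alt_range = c(840, 840),
                  map_range = c(1000, 1000),
                  lgm_multiplier = 1, midh_multiplier = 1, ...)
}

# true (noise-free) atmospheric curves of a scenario on a regular grid
truth_curves <- function(cfg, step = 0.2) {
  tr <- truth_functions_of(cfg)
  age <- seq(0, cfg$age_max, by = step)
  list(pco2 = spline_curve(age, tr$pco2(age)),
       d13c = spline_curve(age, tr$d13c(age)))
}

# one full analysis pass on a seeded synthetic scenario, returning the
# estimated and injected pCO2 effect per 100 ppmv
recover_once <- function(seed, ...) {
  sc <- sim_scenario(scenario_config(seed = seed, ...))
  tr <- attr(sc$records, "truth")
  rec <- adjust_records(sc$records)
  rec$d13c_pe <- plant_equivalent(rec$d13c_adj, rec$archive)
  an <- analyze_cohorts(rec, sc$gcm, value = "d13c_pe",
                        rise_ppmv = tr$rise_ppmv,
                        delta_co2iso = tr$co2iso_shift)
  c(est = an$decomposition$per100, truth = tr$per100,
    sigma = an$decomposition$per100_sigma)
}

# re-derive the generator's truth functions without reaching into internals
truth_functions_of <- function(cfg) {
  old <- cfg
  cfg$pco2_noise <- 0; cfg$d13c_noise <- 0
  ice <- sim_icecore(cfg)
  ice$truth
}
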