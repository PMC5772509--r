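make_samples <- function(age, value, sigma = 0) {
  data.frame(age = age, value = value, sigma = sigma)
}

test_that("MCA spline reproduces degenerate inputs", {
  a <- seq(0, 20, length.out = 50)
  cst <- mca_spline(make_samples(a, 7), n_rep = 5, seed = 1)
  expect_equal(cst$mean, rep(7, nrow(cst)), tolerance = 1e-9)
  expect_equal(cst$sigma, rep(0, nrow(cst)))
  lin <- mca_spline(make_samples(a, 200 + 2 * a), n_rep = 1, seed = 1)
  expect_lt(max(abs(lin$mean - (200 + 2 * lin$age))), 1e-6)
})

test_that("MCA spline tracks a noisy deglacial ramp within its envelope", {
  cfg <- scenario_config(seed = 21, n_pco2 = 120)
  ice <- sim_icecore(cfg)
  truth <- ice$truth$pco2
  cv <- mca_spline(ice$pco2, n_rep = 500, seed = 5)
  inner <- cv$age > 1 & cv$age < cfg$age_max - 1
  cover <- abs(cv$mean - truth(cv$age)) <= 2 * pmax(cv$sigma, 1e-9)
  expect_gt(mean(cover[inner]), 0.95)
})

test_that("MCA spline preconditions and metadata", {
  a <- seq(0, 10, length.out = 30)
  s <- make_samples(a, 100 + a, 1)
  expect_error(mca_spline(s[1:3, ]), "at least 4")
  expect_error(mca_spline(s, grid = seq(-5, 10, 0.1)), "extrapolation")
  # flagged outliers are excluded before fitting
  s2 <- rbind(s, data.frame(age = 5.05, value = 1e4, sigma = 1))
  s2$outlier <- c(rep(FALSE, 30), TRUE)
  ref <- mca_spline(s, n_rep = 10, seed = 3)
  out <- mca_spline(s2, n_rep = 10, seed = 3)
  expect_equal(out$mean, ref$mean)
  expect_identical(attr(out, "cutoff_yr"), 375)
  expect_identical(attr(out, "n_rep"), 10)
})

test_that("spline sigma scales down with measurement noise", {
  a <- seq(0, 20, length.out = 60)
  sig_of <- function(noise) {
    cv <- mca_spline(make_samples(a, 220 + a, noise), n_rep = 200, seed = 8)
    mean(cv$sigma)
  }
  s <- vapply(c(4, 1, 0.25), sig_of, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_lt(s[3], 0.25)
})

test_that("curve mean is stable under reseeding", {
  cfg <- quick_cfg(seed = 4)
  ice <- sim_icecore(cfg)
  c1 <- mca_spline(ice$pco2, n_rep = 400, seed = 1)
  c2 <- mca_spline(ice$pco2, n_rep = 400, seed = 99)
  tol <- 3 * pmax(c1$sigma, 1e-6) / sqrt(400)
  expect_gt(mean(abs(c1$mean - c2$mean) <= tol), 0.95)
})

test_that("anthropogenic merge is continuous and interpolation-grade", {
  a <- seq(0.3, 20, length.out = 80)
  pre <- mca_spline(make_samples(a, 280 - 4 * a), n_rep = 1, seed = 1)
  expect_identical(merge_anthropogenic(pre, NULL), pre)
  expect_identical(merge_anthropogenic(pre, pre[0, ]), pre)
  # dense noiseless exponential rise over the industrial era
  ma <- seq(0, 0.35, by = 0.01)
  ramp <- function(x) 280 + 120 * exp(-x / 0.05)
  mod <- data.frame(age = ma, value = ramp(ma), sigma = 0)
  mg <- merge_anthropogenic(pre, mod)
  young <- mg$age <= 0.3
  expect_lt(max(abs(mg$mean[young] - ramp(mg$age[young]))), 1e-5)
  # no jump anywhere beyond grid-step x max slope
  slope_max <- max(abs(diff(mg$mean) / diff(mg$age)))
  expect_lt(max(abs(diff(mg$mean))), 1.5 * stats::median(diff(mg$age)) * slope_max + 1e-9)
  # a gap wider than one grid step is refused
  far <- data.frame(age = c(0, 0.02, 0.05, 0.08), value = 300, sigma = 0)
  pre_far <- mca_spline(make_samples(seq(5, 20, length.out = 40), 250),
                        n_rep = 1, seed = 1)
  expect_error(merge_anthropogenic(pre_far, far), "gap")
})

test_that("forward-modelled curves propagate uncertainty correctly", {
  age <- seq(0, 30, by = 0.25)
  cfg <- scenario_config(seed = 1)
  tr <- sim_icecore(cfg)$truth
  p0 <- spline_curve(age, tr$pco2(age))
  d0 <- spline_curve(age, tr$d13c(age))
  cv0 <- model_curve("sj2012", p0, d0, n_rep = 50, seed = 2)
  expect_equal(cv0$sigma, rep(0, length(age)))          # exact inputs
  expect_equal(cv0$mean, predict_delta_p("sj2012", p0$mean, d0$mean))
  # Farquhar-1982 is d13C_CO2 plus a constant: sigma tracks the d13C curve
  ds <- spline_curve(age, tr$d13c(age), sigma = 0.1)
  ps <- spline_curve(age, tr$pco2(age), sigma = 3)
  cvf <- model_curve("farquhar1982", ps, ds, n_rep = 3000, seed = 2)
  expect_equal(mean(cvf$sigma), 0.1, tolerance = 0.05)
  expect_error(model_curve("sj2012", p0, spline_curve(age + 1, d0$mean)),
               "grid")
})

test_that("expanded uncertainty combines the modern spread in quadrature", {
  expect_equal(expanded_uncertainty(0), 1.62)
  expect_equal(expanded_uncertainty(1.62), sqrt(2) * 1.62)
  expect_equal(expanded_uncertainty(0.7, modern_spread = 0), 0.7)
  expect_error(expanded_uncertainty(-1), ">= 0")
})

test_that("episode detection finds constructed ramps and nothing else", {
  age <- seq(0, 30, by = 0.1)
  flat <- spline_curve(age, rep(-25, length(age)))
  expect_equal(nrow(detect_episodes(flat)), 0)
  # 1.5 per mil over 3 kyr (rate 0.5/kyr) amid flat background
  v <- ifelse(age < 10, 0, ifelse(age > 13, 1.5, (age - 10) * 0.5))
  ep <- detect_episodes(spline_curve(age, v))
  expect_equal(nrow(ep), 1)
  expect_lt(abs(ep$end - 10), 0.1 + 1e-9)
  expect_lt(abs(ep$start - 13), 0.2 + 1e-9)
  expect_equal(ep$amplitude, 1.45, tolerance = 0.1)
  expect_equal(ep$mean_rate, 0.5, tolerance = 0.05)
})

test_that("episodes are disjoint, ordered oldest-first, and monotone in amp_min", {
  age <- seq(0, 40, by = 0.1)
  v <- 1.6 * plogis((age - 14) / 0.8) + 1.4 * plogis((age - 30) / 0.7) +
       0.3 * sin(age)
  cv <- spline_curve(age, v)
  ep <- detect_episodes(cv)
  if (nrow(ep) > 1) {
    expect_true(all(diff(ep$start) < 0))              # oldest first
    expect_true(all(ep$end[-nrow(ep)] > ep$start[-1])) # disjoint
  }
  lo <- detect_episodes(cv, amp_min = 0.5)
  # lowering the amplitude threshold only adds episodes
  expect_true(all(ep$start %in% lo$start))
  expect_gte(nrow(lo), nrow(ep))
  # the recent anthropogenic window is excluded
  v2 <- v + ifelse(age < 0.15, -3 * (0.15 - age) / 0.15, 0)
  ep2 <- detect_episodes(spline_curve(age, v2), exclude_after = 0.2)
  expect_true(all(ep2$end >= 0.2))
})
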