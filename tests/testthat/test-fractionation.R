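test_that("ci/ca strategies evaluate as specified", {
  expect_equal(ci_ca(farquhar_params(ci_ca = 0.6), 190), 0.6)
  expect_equal(ci_ca(farquhar_params(ci_ca = 0.6), c(150, 400)), c(0.6, 0.6))
  # gymnosperm and angiosperm linear strategies, hand-evaluated
  g <- fractionation_model("voelker2016g")$params
  expect_equal(ci_ca(g, 280), 0.6084, tolerance = 1e-10)
  a <- fractionation_model("voelker2016a")$params
  expect_equal(ci_ca(a, 400), 0.773, tolerance = 1e-10)
  expect_error(ci_ca(g, -10), "> 0")
  expect_warning(ci_ca(g, 5000), "clamped")
  expect_true(all(suppressWarnings(ci_ca(g, c(1, 5000))) > 0 &
                  suppressWarnings(ci_ca(g, c(1, 5000))) < 1))
})

test_that("Farquhar-type plant d13C matches hand evaluations", {
  # modern global-mean anchor: ci/ca = 0.6, d13C_CO2 = -8.4 -> ~-27.1
  p <- farquhar_params(ci_ca = 0.6)
  expect_equal(delta_p_farquhar(p, 400, -8.4), -27.08, tolerance = 1e-12)
  # gymnosperm strategy at glacial CO2: -6.5 - 4.4 - 23.8 * 0.5742
  g <- fractionation_model("voelker2016g")$params
  expect_equal(delta_p_farquhar(g, 190, -6.5), -24.56596, tolerance = 1e-6)
  expect_warning(delta_p_farquhar(p, 400, -25), "implausible")
  expect_error(farquhar_params(a = 30, b = 28.2, ci_ca = 0.6), "a < b")
})

test_that("hyperbolic discrimination is correct, monotone and bounded", {
  s <- sj_params()
  expect_equal(discrimination_sj(s, 400), 28.26 * 93.258 / 121.518,
               tolerance = 1e-12)
  expect_equal(discrimination_sj(s, 280), 19.86374, tolerance = 1e-5)
  grid <- seq(1, 5000, length.out = 1000)
  d <- discrimination_sj(s, grid)
  expect_true(all(diff(d) > 0))
  expect_true(all(d < s$A))
  expect_error(discrimination_sj(s, 0), "> 0")
})

test_that("discrimination <-> delta_p conversions are exact inverses", {
  expect_equal(delta_p_from_discrimination(-7.2, 0), -7.2)
  expect_equal(delta_p_from_discrimination(-6.5, 19.864),
               (-6.5 - 19.864) / 1.019864, tolerance = 1e-12)
  expect_equal(delta_p_from_discrimination(-6.5, 19.864), -25.85,
               tolerance = 1e-4)
  set.seed(11)
  dp <- runif(200, -35, -20); da <- runif(200, -9, -6)
  dd <- discrimination_from_delta_p(da, dp)
  expect_equal(delta_p_from_discrimination(da, dd), dp, tolerance = 1e-12)
  expect_error(delta_p_from_discrimination(-6.5, -1000), "singular")
})

test_that("model registry dispatches and predicts the deglacial change", {
  expect_equal(fractionation_model("SJ-2012")$name, "SJ-2012")
  expect_equal(fractionation_model("voelker2016g")$k, 4)
  expect_error(fractionation_model("nonesuch"), "unknown model")
  expect_error(fractionation_model("sj2012", farquhar_params(ci_ca = 0.5)),
               "sj_params")
  # 190 -> 270 ppmv at fixed d13C_CO2
  ch <- function(m) diff(predict_delta_p(m, c(190, 270), -6.5))
  expect_equal(ch("sj2012"), -1.922948, tolerance = 1e-6)
  expect_equal(ch("farquhar1982"), 0)            # constant ci/ca: no effect
  expect_equal(ch("voelker2016g"), -23.8 * 0.00038 * 80, tolerance = 1e-12)
  # custom constants are honoured
  m <- fractionation_model("sj2012", sj_params(A = 30, B = 0.22, C = 23.9))
  expect_equal(discrimination_sj(m$params, 1e9), 30, tolerance = 1e-5)
})

test_that("sensitivity to ca matches the analytic derivative", {
  # linear ci/ca strategy: d(delta_p)/d(ca) = -(b - a) * slope
  g <- fractionation_model("voelker2016g")$params
  h <- 1e-4
  for (ca in c(190, 280, 400)) {
    fd <- (delta_p_farquhar(g, ca + h, -6.5) -
           delta_p_farquhar(g, ca - h, -6.5)) / (2 * h)
    expect_equal(fd, -(28.2 - 4.4) * 0.00038, tolerance = 1e-6)
  }
})

test_that("a source-d13C shift propagates through each model family", {
  s <- 0.37
  for (nm in c("farquhar1982", "voelker2016a", "voelker2016g")) {
    m <- fractionation_model(nm)
    expect_equal(predict_delta_p(m, 250, -6.5 + s) -
                 predict_delta_p(m, 250, -6.5), s, tolerance = 1e-12)
  }
  # the hyperbolic model passes the shift through the exact inversion:
  # the response is s / (1 + Delta/1000), not s itself
  m <- fractionation_model("sj2012")
  dd <- discrimination_sj(m$params, 250)
  expect_equal(predict_delta_p(m, 250, -6.5 + s) -
               predict_delta_p(m, 250, -6.5),
               s / (1 + dd / 1000), tolerance = 1e-12)
})
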