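#' Quadrature combination of independent uncertainties
#'
#' @param ... non-negative 1-sigma uncertainties (numbers or vectors; all
#'   values are pooled).
#' @return `sqrt(sum(sigma_i^2))`.
#' @examples
#' quadrature(3, 4)        # 5
#' quadrature(1.62, 1.62)  # sqrt(2) * 1.62
#' @export
quadrature <- function(...) {
  s <- c(...)
  if (any(s < 0)) stop("uncertainties must be >= 0")
  sqrt(sum(s^2))
}

#' Rescale a deglacial effect to per-100-ppmv units
#'
#' Linear rescaling of an isotopic effect (and its 1-sigma) observed over
#' the deglacial CO2 rise to a standard 100 ppmv of CO2 change.
#'
#' @param effect effect over the rise, per mil.
#' @param sigma its 1-sigma uncertainty, per mil (default 0).
#' @param rise_ppmv the CO2 rise the effect was observed over, ppmv
#'   (default 80.5, the deglacial rise between the >20 kyr and <10 kyr
#'   window means).
#' @return list with `mean` and `sigma`, per mil per 100 ppmv.
#' @examples
#' per_100ppmv(-0.53)  # about -0.66
#' @export
per_100ppmv <- function(effect, sigma = 0, rise_ppmv = 80.5) {
  if (rise_ppmv <= 0) stop("'rise_ppmv' must be > 0")
  list(mean = effect * 100 / rise_ppmv, sigma = sigma * 100 / rise_ppmv)
}

#' Decompose the deglacial d13C shift into pCO2 and MAP components
#'
#' The change in geographically adjusted mean d13C between the Holocene and
#' pre-glacial windows is modelled as the sum of three contributions:
#' changing pCO2, changing MAP, and the change in atmospheric d13C_CO2
#' itself (about 0.05 per mil between the window means, negligible and
#' dropped by default). The pCO2 effect is the residual
#' `delta_pco2 = delta_adj - delta_map - delta_co2iso`, with uncertainty
#' combined in quadrature, and is also rescaled to per-100-ppmv units.
#'
#' @param delta_adj Holocene-minus-preglacial difference of adjusted group
#'   means, per mil.
#' @param sigma_adj its 1-sigma (e.g. the standard error of the difference
#'   of means), per mil.
#' @param delta_map MAP contribution (e.g. from [cohort_map_effect()]),
#'   per mil.
#' @param sigma_map its 1-sigma, per mil.
#' @param delta_co2iso d13C_CO2 source-change term, per mil; default 0
#'   (dropped). Pass 0.05 to retain it.
#' @param sigma_co2iso its 1-sigma (default 0, treated as exact).
#' @param rise_ppmv deglacial CO2 rise, ppmv (default 80.5).
#' @return object of class `"effect_decomposition"`: a list with the input
#'   components, the residual `delta_pco2` (+ `sigma_pco2`), and `per100`
#'   (+ `per100_sigma`).
#' @examples
#' decompose_shift(delta_adj = -0.93, delta_map = -0.4)
#' @export
decompose_shift <- function(delta_adj, sigma_adj = 0, delta_map = 0,
                            sigma_map = 0, delta_co2iso = 0,
                            sigma_co2iso = 0, rise_ppmv = 80.5) {
  delta_pco2 <- delta_adj - delta_map - delta_co2iso
  sigma_pco2 <- quadrature(sigma_adj, sigma_map, sigma_co2iso)
  p <- per_100ppmv(delta_pco2, sigma_pco2, rise_ppmv)
  structure(list(delta_adj = delta_adj, sigma_adj = sigma_adj,
                 delta_map = delta_map, sigma_map = sigma_map,
                 delta_co2iso = delta_co2iso, sigma_co2iso = sigma_co2iso,
                 delta_pco2 = delta_pco2, sigma_pco2 = sigma_pco2,
                 per100 = p$mean, per100_sigma = p$sigma,
                 rise_ppmv = rise_ppmv),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, digits = 3, ...) {
  f <- function(m, s) if (s > 0) sprintf("%.*g +/- %.*g", digits, m, digits, s)
                      else sprintf("%.*g", digits, m)
  cat("<effect_decomposition> (per mil, Holocene minus pre-glacial)\n")
  cat("  adjusted shift   :", f(x$delta_adj, x$sigma_adj), "\n")
  cat("  MAP contribution :", f(x$delta_map, x$sigma_map), "\n")
  if (x$delta_co2iso != 0)
    cat("  d13C_CO2 term    :", f(x$delta_co2iso, x$sigma_co2iso), "\n")
  cat("  pCO2 residual    :", f(x$delta_pco2, x$sigma_pco2), "\n")
  cat(sprintf("  per 100 ppmv     : %s  (rise %.4g ppmv)\n",
              f(x$per100, x$per100_sigma), x$rise_ppmv))
  invisible(x)
}

#' One-sided test for the deglacial shift in group means
#'
#' Tests whether post-glacial (Holocene) d13C values are more negative than
#' pre-glacial values. Implemented as a one-sided Welch two-sample t-test
#' of `post` against `pre` (`alternative = "less"`); there is no natural
#' pairing between the two differently aged cohorts, so a paired test is
#' not meaningful here.
#'
#' @param pre,post numeric vectors of (adjusted) d13C values in the
#'   pre-glacial and Holocene windows.
#' @param alternative passed to [stats::t.test()]; default `"less"`
#'   (post more negative than pre).
#' @return an object of class `"htest"`.
#' @export
group_shift_test <- function(pre, post, alternative = "less") {
  if (length(pre) < 2L || length(post) < 2L)
    stop("both groups need at least 2 values")
  t.test(post, pre, alternative = alternative, var.equal = FALSE)
}
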