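#' Parameters for Farquhar-type fractionation models
#'
#' The classical model of C3 photosynthetic carbon isotope fractionation
#' combines fractionation during gaseous diffusion through the boundary layer
#' and stomata (`a`, per mil) with net discrimination during carboxylation
#' (`b`, per mil), weighted by the ratio of leaf-intercellular to atmospheric
#' CO2 partial pressure (ci/ca):
#'
#' \deqn{\delta^{13}C_p = \delta^{13}C_{CO_2} - a - (b - a)\, c_i/c_a}
#'
#' Two leaf gas-exchange strategies are supported: a constant ci/ca ratio,
#' and a linear dependence of ci/ca on atmospheric CO2 concentration
#' (`ci/ca = slope * ca + intercept`), the latter describing the dynamic
#' stomatal response inferred for gymnosperms and woody angiosperms.
#'
#' @param a diffusion fractionation, per mil. Default 4.4, from the reduced
#'   masses of the 13CO2 and 12CO2 isotopologues.
#' @param b net carboxylation discrimination, per mil. Default 28.2.
#' @param ci_ca constant ci/ca ratio in (0, 1), or `NULL` when a linear
#'   strategy is given.
#' @param slope,intercept coefficients of the linear ci/ca(ca) strategy
#'   (slope in 1/ppmv). Supply both, or neither.
#' @return An object of class `"farquhar_params"`.
#' @seealso [fractionation_model()] for the named model registry.
#' @examples
#' farquhar_params(ci_ca = 0.6)
#' farquhar_params(slope = 0.00038, intercept = 0.502)  # gymnosperm strategy
#' @export
farquhar_params <- function(a = 4.4, b = 28.2, ci_ca = NULL,
                            slope = NULL, intercept = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!(a > 0 && b > a))
    stop("require 0 < a < b (per mil fractionations)")
  has_const <- !is.null(ci_ca)
  has_lin <- !is.null(slope) || !is.null(intercept)
  if (has_const && has_lin)
    stop("give either a constant 'ci_ca' or a linear 'slope'/'intercept' strategy, not both")
  if (has_const) {
    if (!(ci_ca > 0 && ci_ca < 1)) stop("constant ci_ca must lie in (0, 1)")
    strategy <- list(type = "constant", r = ci_ca)
  } else if (has_lin) {
    if (is.null(slope) || is.null(intercept))
      stop("linear strategy needs both 'slope' and 'intercept'")
    strategy <- list(type = "linear", slope = slope, intercept = intercept)
  } else stop("no ci/ca strategy given")
  structure(list(a = a, b = b, strategy = strategy),
            class = "farquhar_params")
}

#' Parameters of the hyperbolic (Schubert-Jahren) discrimination model
#'
#' Constants of the hyperbolic dependence of C3 discrimination on CO2
#' concentration, fitted to growth-chamber experiments and Last Glacial
#' fossil data spanning 180-4200 ppmv. `A` (per mil) is the discrimination
#' asymptote at high pCO2, `B` (per mil/ppmv) the initial slope scale, and
#' `C` (ppmv) an offset.
#'
#' @param A,B,C model constants; defaults 28.26, 0.22, 23.9.
#' @return An object of class `"sj_params"`.
#' @export
sj_params <- function(A = 28.26, B = 0.22, C = 23.9) {
  if (!(A > 0 && B > 0 && C > 0)) stop("A, B and C must all be > 0")
  structure(list(A = A, B = B, C = C), class = "sj_params")
}

#' Evaluate the ci/ca ratio of a Farquhar-type model
#'
#' Constant strategies return their ratio irrespective of `ca`; linear
#' strategies return `slope * ca + intercept`, clamped to the open interval
#' (0, 1) with a warning, since a ratio outside that range is unphysical.
#'
#' @param params a [farquhar_params()] object.
#' @param ca atmospheric CO2 concentration, ppmv (vectorised, all > 0).
#' @return numeric vector of ci/ca ratios.
#' @export
ci_ca <- function(params, ca) {
  stopifnot(inherits(params, "farquhar_params"))
  if (any(!is.finite(ca)) || any(ca <= 0))
    stop("'ca' must be finite and > 0 (ppmv)")
  s <- params$strategy
  if (s$type == "constant") return(rep(s$r, length(ca)))
  r <- s$slope * ca + s$intercept
  lo <- 1e-6
  if (any(r <= 0 | r >= 1)) {
    warning("ci/ca outside (0, 1); clamped")
    r <- pmin(pmax(r, lo), 1 - lo)
  }
  r
}

#' Plant d13C from a Farquhar-type model
#'
#' Applies the linear-in-delta form of the diffusion/carboxylation model:
#' `d13C_p = d13C_CO2 - a - (b - a) * ci/ca`.
#'
#' @param params a [farquhar_params()] object.
#' @param pco2 atmospheric CO2 concentration, ppmv.
#' @param d13c_co2 d13C of atmospheric CO2, per mil VPDB. Values outside
#'   \[-20, 0\] trigger a warning (physically implausible for air).
#' @return d13C of C3 plant tissue, per mil VPDB.
#' @examples
#' # modern global-mean C3 plant value
#' delta_p_farquhar(farquhar_params(ci_ca = 0.6), pco2 = 400, d13c_co2 = -8.4)
#' @export
delta_p_farquhar <- function(params, pco2, d13c_co2) {
  check_d13c_co2(d13c_co2)
  r <- ci_ca(params, pco2)
  d13c_co2 - params$a - (params$b - params$a) * r
}

check_d13c_co2 <- function(x) {
  if (any(is.finite(x) & (x < -20 | x > 0)))
    warning("d13c_co2 outside [-20, 0] per mil: implausible for atmospheric CO2")
  invisible(x)
}

#' Hyperbolic discrimination as a function of pCO2
#'
#' Evaluates `Delta13C = A*B*(pCO2 + C) / (A + B*(pCO2 + C))`, a saturating
#' hyperbola that is strictly increasing in pCO2 and bounded above by `A`.
#'
#' @param params an [sj_params()] object.
#' @param pco2 CO2 concentration, ppmv (> 0).
#' @return photosynthetic discrimination Delta13C, per mil.
#' @export
discrimination_sj <- function(params, pco2) {
  stopifnot(inherits(params, "sj_params"))
  if (any(!is.finite(pco2)) || any(pco2 <= 0))
    stop("'pco2' must be finite and > 0 (ppmv)")
  u <- params$B * (pco2 + params$C)
  params$A * u / (params$A + u)
}

#' Convert between discrimination and plant d13C
#'
#' Discrimination is defined as
#' `Delta13C = (d13C_CO2 - d13C_p) / (1 + d13C_p/1000)`;
#' [delta_p_from_discrimination()] is its exact algebraic inversion,
#' `d13C_p = (d13C_CO2 - Delta) / (1 + Delta/1000)`, and
#' [discrimination_from_delta_p()] the forward form. The two are exact
#' inverses of one another.
#'
#' @param d13c_co2 d13C of atmospheric CO2, per mil VPDB.
#' @param big_delta discrimination Delta13C, per mil (> -1000).
#' @param delta_p plant d13C, per mil VPDB (> -1000).
#' @return per mil value (plant d13C, or discrimination).
#' @export
delta_p_from_discrimination <- function(d13c_co2, big_delta) {
  if (any(big_delta <= -1000))
    stop("discrimination <= -1000 per mil is singular")
  (d13c_co2 - big_delta) / (1 + big_delta / 1000)
}

#' @rdname delta_p_from_discrimination
#' @export
discrimination_from_delta_p <- function(d13c_co2, delta_p) {
  if (any(delta_p <= -1000)) stop("delta_p <= -1000 per mil is singular")
  (d13c_co2 - delta_p) / (1 + delta_p / 1000)
}

# canonical names and constructor defaults for the four-model registry
.model_registry <- list(
  `farquhar1982` = list(
    name = "Farquhar-1982", k = 3,
    params = function() farquhar_params(ci_ca = 0.6)),
  `voelker2016a` = list(
    name = "Voelker-2016a", k = 4,
    params = function() farquhar_params(slope = 0.00031, intercept = 0.649)),
  `voelker2016g` = list(
    name = "Voelker-2016g", k = 4,
    params = function() farquhar_params(slope = 0.00038, intercept = 0.502)),
  `sj2012` = list(
    name = "SJ-2012", k = 3,
    params = function() sj_params())
)

#' The four standard fractionation models
#'
#' A registry of the four forward models considered for the deglacial
#' analysis:
#' \describe{
#'   \item{Farquhar-1982}{constant ci/ca = 0.6 with a = 4.4, b = 28.2 per
#'     mil; pCO2-independent at fixed atmospheric d13C, chosen because it
#'     reproduces the modern global-mean plant value of about -27.1 per mil.}
#'   \item{Voelker-2016g}{gymnosperm strategy, ci/ca = 0.00038 ca + 0.502.}
#'   \item{Voelker-2016a}{woody-angiosperm strategy, ci/ca = 0.00031 ca + 0.649.}
#'   \item{SJ-2012}{the hyperbolic discrimination model with A = 28.26,
#'     B = 0.22, C = 23.9, converted to plant d13C through the exact
#'     discrimination definition.}
#' }
#' Names are matched case-insensitively, ignoring punctuation
#' (`"SJ-2012"`, `"sj2012"`, ...). All constants can be overridden by
#' passing a `params` object.
#'
#' @param name model name.
#' @param params optional [farquhar_params()] or [sj_params()] object
#'   overriding the registry defaults (kind must match the model family).
#' @return An object of class `"fractionation_model"` with elements `name`,
#'   `params` and `k` (free-parameter count used for AIC/BIC).
#' @examples
#' fractionation_model("sj2012")
#' fractionation_model("Voelker-2016g")
#' @export
fractionation_model <- function(name, params = NULL) {
  key <- gsub("[^a-z0-9]", "", tolower(name))
  if (!key %in% names(.model_registry))
    stop(sprintf("unknown model '%s'; available: %s", name,
                 paste(vapply(.model_registry, `[[`, "", "name"),
                       collapse = ", ")))
  entry <- .model_registry[[key]]
  if (is.null(params)) params <- entry$params()
  want <- if (key == "sj2012") "sj_params" else "farquhar_params"
  if (!inherits(params, want))
    stop(sprintf("model '%s' requires params of class '%s'", entry$name, want))
  structure(list(name = entry$name, params = params, k = entry$k),
            class = "fractionation_model")
}

#' @export
print.fractionation_model <- function(x, ...) {
  cat("<fractionation_model>", x$name, "\n")
  p <- x$params
  if (inherits(p, "sj_params")) {
    cat(sprintf("  Delta13C = A B (pCO2+C)/(A + B (pCO2+C));  A=%.4g B=%.4g C=%.4g\n",
                p$A, p$B, p$C))
  } else {
    s <- p$strategy
    ss <- if (s$type == "constant") sprintf("ci/ca = %.4g", s$r)
          else sprintf("ci/ca = %.5g ca + %.4g", s$slope, s$intercept)
    cat(sprintf("  d13Cp = d13C_CO2 - a - (b-a) ci/ca;  a=%.3g b=%.3g, %s\n",
                p$a, p$b, ss))
  }
  invisible(x)
}

#' Predict plant d13C under a named fractionation model
#'
#' Dispatches over the model family: Farquhar-type models evaluate the
#' linear-in-delta expression directly, while the hyperbolic model composes
#' [discrimination_sj()] with the exact discrimination-to-delta inversion
#' [delta_p_from_discrimination()].
#'
#' @param model a [fractionation_model()] object (or a name accepted by it).
#' @param pco2 atmospheric CO2 concentration, ppmv (vectorised).
#' @param d13c_co2 atmospheric d13C_CO2, per mil VPDB (vectorised,
#'   recycled against `pco2`).
#' @return d13C of C3 plant tissue, per mil VPDB.
#' @examples
#' m <- fractionation_model("sj2012")
#' # plant d13C change across the deglacial CO2 rise at fixed source d13C
#' diff(predict_delta_p(m, pco2 = c(190, 270), d13c_co2 = -6.5))
#' @export
predict_delta_p <- function(model, pco2, d13c_co2) {
  if (is.character(model)) model <- fractionation_model(model)
  stopifnot(inherits(model, "fractionation_model"))
  if (inherits(model$params, "sj_params")) {
    check_d13c_co2(d13c_co2)
    dd <- discrimination_sj(model$params, pco2)
    delta_p_from_discrimination(d13c_co2, dd)
  } else {
    delta_p_farquhar(model$params, pco2, d13c_co2)
  }
}
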