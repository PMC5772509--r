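#' Residuals of proxy records against a model curve
#'
#' Interpolates the curve mean linearly to each record's age and returns
#' `value - prediction`. Records whose ages fall outside the curve span are
#' dropped with a message (no extrapolation); the number dropped is stored
#' in the `"n_skipped"` attribute.
#'
#' @param curve a [spline_curve()] of predicted plant d13C.
#' @param age record ages, kyr BP.
#' @param value record plant-equivalent d13C, per mil VPDB (convert faunal
#'   collagen with [collagen_to_plant()] first).
#' @return numeric vector of residuals, per mil.
#' @export
curve_residuals <- function(curve, age, value) {
  stopifnot(inherits(curve, "spline_curve"), length(age) == length(value))
  ok <- age >= min(curve$age) & age <= max(curve$age)
  if (any(!ok))
    message(sum(!ok), " record(s) outside the curve span were skipped")
  pred <- approx(curve$age, curve$mean, xout = age[ok])$y
  r <- value[ok] - pred
  attr(r, "n_skipped") <- sum(!ok)
  r
}

#' Root mean square error of residuals
#'
#' @param residuals numeric vector (n >= 1).
#' @return `sqrt(mean(residuals^2))`, per mil.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0L) stop("no residuals")
  sqrt(mean(residuals^2))
}

#' Gaussian information criteria from residuals
#'
#' Scores a model with `k` free parameters against its residuals under a
#' Gaussian error model whose variance is set at its maximum-likelihood
#' value `mean(r^2)`. The maximised log-likelihood is then
#' `-n/2 (log(2 pi) + log(s2) + 1)`, with `aic = 2k - 2 logLik` and
#' `bic = log(n) k - 2 logLik`. A fixed error scale can be imposed instead
#' via `sigma`.
#'
#' @param residuals numeric vector (n >= 2).
#' @param k number of free model parameters.
#' @param sigma optional fixed residual standard deviation, per mil;
#'   `NULL` (default) uses the MLE.
#' @return list with `n`, `k`, `loglik`, `aic`, `bic`.
#' @export
information_criteria <- function(residuals, k, sigma = NULL) {
  n <- length(residuals)
  if (n < 2L) stop("need at least 2 residuals")
  s2 <- if (is.null(sigma)) mean(residuals^2) else sigma^2
  if (s2 <= 0) stop("residual variance is zero; likelihood is unbounded")
  ll <- if (is.null(sigma)) -n / 2 * (log(2 * pi) + log(s2) + 1)
        else -n / 2 * log(2 * pi * s2) - sum(residuals^2) / (2 * s2)
  list(n = n, k = k, loglik = ll, aic = 2 * k - 2 * ll,
       bic = log(n) * k - 2 * ll)
}

#' Score fractionation models against an adjusted proxy record
#'
#' For each model, forward-models a plant d13C curve from the atmospheric
#' curves, computes record residuals and reports RMSE, AIC and BIC. Faunal
#' or cellulose records must already be on the scale being compared
#' (typically plant-equivalent adjusted d13C).
#'
#' @param models list of [fractionation_model()] objects or names; default
#'   all four registry models.
#' @param pco2_curve,d13c_curve atmospheric [spline_curve()]s on a shared
#'   grid.
#' @param age,value record ages (kyr BP) and d13C values (per mil).
#' @param sigma optional fixed error scale for the likelihood (see
#'   [information_criteria()]).
#' @return data frame with columns `model`, `n`, `k`, `rmse`, `loglik`,
#'   `aic`, `bic`, sorted by increasing BIC.
#' @export
score_models <- function(models = names_of_models(), pco2_curve, d13c_curve,
                         age, value, sigma = NULL) {
  rows <- lapply(models, function(m) {
    if (is.character(m)) m <- fractionation_model(m)
    cv <- model_curve(m, pco2_curve, d13c_curve, n_rep = 1)
    r <- curve_residuals(cv, age, value)
    ic <- information_criteria(r, m$k, sigma = sigma)
    data.frame(model = m$name, n = ic$n, k = ic$k, rmse = rmse(r),
               loglik = ic$loglik, aic = ic$aic, bic = ic$bic)
  })
  out <- do.call(rbind, rows)
  out[order(out$bic), , drop = FALSE]
}

#' @rdname score_models
#' @export
names_of_models <- function() {
  vapply(.model_registry, `[[`, "", "name")
}
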