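#' Construct a curve object on a regular age grid
#'
#' A `spline_curve` is a data frame with columns `age` (kyr BP, strictly
#' increasing), `mean` and `sigma` (pointwise 1-sigma uncertainty), the
#' common currency of the curve-building and forward-modelling steps.
#'
#' @param age age grid, kyr BP (BP = 1950 CE), strictly increasing.
#' @param mean curve value at each grid point (ppmv or per mil).
#' @param sigma pointwise 1-sigma uncertainty (same units, >= 0).
#' @param ... further attributes recorded as metadata (e.g. `cutoff_yr`,
#'   `n_rep`, `seed`, `perturb`).
#' @return a data frame of class `"spline_curve"`.
#' @export
spline_curve <- function(age, mean, sigma = 0, ...) {
  stopifnot(length(age) == length(mean))
  if (any(diff(age) <= 0)) stop("'age' must be strictly increasing")
  sigma <- rep_len(sigma, length(age))
  if (any(sigma < 0)) stop("'sigma' must be >= 0")
  out <- data.frame(age = age, mean = mean, sigma = sigma)
  class(out) <- c("spline_curve", "data.frame")
  meta <- list(...)
  for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
  out
}

#' @export
print.spline_curve <- function(x, ...) {
  cat(sprintf("<spline_curve> %d points, %.3g-%.3g kyr BP (step %.3g kyr)\n",
              nrow(x), min(x$age), max(x$age), stats::median(diff(x$age))))
  if (!is.null(attr(x, "cutoff_yr")))
    cat(sprintf("  cutoff %.0f yr, %d replicates, perturb = %s, seed = %s\n",
                attr(x, "cutoff_yr"), attr(x, "n_rep") %||% NA_integer_,
                attr(x, "perturb") %||% "?",
                format(attr(x, "seed") %||% NA)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

# smoothing parameter for smooth.spline such that the spline's amplitude
# response is ~50% at period `cutoff` (same units as x).  In the continuous
# limit the penalized fit acts as a low-pass filter with response
# 1/(1 + (mu/rho)(2 pi f)^4), rho = point density; smooth.spline penalizes
# curvature on x scaled to [0,1], hence the r^3 rescaling.
cutoff_lambda <- function(x, cutoff) {
  r <- diff(range(x))
  rho <- length(x) / r
  mu <- rho * (cutoff / (2 * pi))^4
  mu / r^3
}

#' Monte Carlo average smoothing spline for irregular noisy series
#'
#' Builds a continuous curve with uncertainty from irregularly spaced
#' measurements with individual 1-sigma errors (e.g. an ice-core CO2 or
#' d13C_CO2 compilation). For each of `n_rep` replicates every sample value
#' is perturbed by a random draw from its error distribution and a cubic
#' smoothing spline is fitted whose stiffness is set so that variability on
#' periods shorter than `cutoff_yr` is attenuated (50% amplitude response at
#' the cutoff period). The returned curve is the pointwise mean and standard
#' deviation of the replicate fits on a regular age grid. No extrapolation:
#' the grid is confined to the data span.
#'
#' @param samples data frame with columns `age` (kyr BP), `value`, `sigma`
#'   (1-sigma measurement error) and optionally `core` (source identifier)
#'   and `outlier` (logical/0-1; flagged rows are dropped before fitting).
#' @param cutoff_yr cutoff period in years (default 375). Use 0 for an
#'   interpolation-grade fit with negligible smoothing.
#' @param n_rep number of Monte Carlo replicates (default 1000).
#' @param grid optional explicit age grid; must lie within the data span.
#' @param grid_step grid spacing in kyr used when `grid` is NULL
#'   (default 0.1).
#' @param seed integer seed for the replicate perturbations; recorded in the
#'   output metadata. `NULL` uses (and advances) the current RNG stream.
#' @param perturb `"gaussian"` draws N(0, sigma) perturbations,
#'   `"uniform"` draws from +-1 sigma uniformly.
#' @param lambda optional explicit smoothing parameter passed straight to
#'   [stats::smooth.spline()], overriding the cutoff mapping.
#' @return a [spline_curve()] with metadata attributes `cutoff_yr`, `n_rep`,
#'   `perturb`, `seed`, `n_samples`.
#' @examples
#' a <- seq(0, 20, length.out = 60)
#' s <- data.frame(age = a, value = 200 + 2 * a, sigma = 0)
#' cv <- mca_spline(s, n_rep = 1, seed = 1)
#' max(abs(cv$mean - (200 + 2 * cv$age)))  # line recovered
#' @export
mca_spline <- function(samples, cutoff_yr = 375, n_rep = 1000,
                       grid = NULL, grid_step = 0.1, seed = NULL,
                       perturb = c("gaussian", "uniform"), lambda = NULL) {
  perturb <- match.arg(perturb)
  stopifnot_cols(samples, c("age", "value", "sigma"), "samples")
  if (!is.null(samples$outlier))
    samples <- samples[!as.logical(samples$outlier), , drop = FALSE]
  samples <- samples[is.finite(samples$age) & is.finite(samples$value), ,
                     drop = FALSE]
  if (any(samples$sigma < 0)) stop("sample 'sigma' must be >= 0")
  # collapse duplicate ages (smooth.spline averages internally, but we need
  # consistent perturbation bookkeeping)
  o <- order(samples$age)
  samples <- samples[o, , drop = FALSE]
  if (nrow(samples) < 4L)
    stop("need at least 4 usable (non-outlier) samples for a spline fit")
  if (n_rep < 1L) stop("'n_rep' must be >= 1")
  span <- range(samples$age)
  if (is.null(grid)) {
    grid <- seq(span[1], span[2], by = grid_step)
    if (max(grid) < span[2] - 1e-9) grid <- c(grid, span[2])
  } else if (min(grid) < span[1] - 1e-9 || max(grid) > span[2] + 1e-9) {
    stop("'grid' extends beyond the data span; extrapolation is not supported")
  }
  if (is.null(lambda) && cutoff_yr > 0)
    lambda <- cutoff_lambda(samples$age, cutoff_yr / 1000)
  fit_one <- function(y) {
    if (is.null(lambda) || lambda <= 0) {
      f <- splinefun(samples$age, ave_dup(samples$age, y), method = "natural")
      f(grid)
    } else {
      f <- smooth.spline(samples$age, y, lambda = lambda, all.knots = TRUE,
                         keep.data = FALSE)
      predict(f, grid)$y
    }
  }
  reps <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      eps <- switch(perturb,
        gaussian = rnorm(nrow(samples), 0, samples$sigma),
        uniform  = runif(nrow(samples), -samples$sigma, samples$sigma))
      fit_one(samples$value + eps)
    }, numeric(length(grid)))
  })
  m <- rowMeans(reps)
  s <- if (n_rep > 1) apply(reps, 1L, sd) else rep(0, length(grid))
  spline_curve(grid, m, s, cutoff_yr = cutoff_yr, n_rep = n_rep,
               perturb = perturb, seed = seed, n_samples = nrow(samples))
}

# average y over tied x (for the interpolating-spline path)
ave_dup <- function(x, y) {
  if (!anyDuplicated(x)) return(y)
  tapply_y <- tapply(y, x, mean)
  as.numeric(tapply_y[match(x, names(tapply_y))])
}

#' Splice an anthropogenic-era segment onto a pre-industrial curve
#'
#' The recent, densely sampled anthropogenic records are fitted with a cubic
#' spline *without* a cutoff period (the rapid industrial rise is signal,
#' not noise) and combined with the pre-industrial curve. Where the two
#' overlap, the modern fit takes precedence from its oldest sample onward,
#' with a linear cross-fade over one grid step at the junction so the
#' combined curve is continuous.
#'
#' @param pre_industrial a [spline_curve()] for the pre-industrial record.
#' @param modern_samples data frame of modern samples (`age`, `value`,
#'   `sigma`, optional `outlier`); an empty/`NULL` set returns
#'   `pre_industrial` unchanged.
#' @return a [spline_curve()] spanning both segments.
#' @export
merge_anthropogenic <- function(pre_industrial, modern_samples) {
  stopifnot(inherits(pre_industrial, "spline_curve"))
  if (is.null(modern_samples) || nrow(modern_samples) == 0L)
    return(pre_industrial)
  stopifnot_cols(modern_samples, c("age", "value"), "modern_samples")
  if (!is.null(modern_samples$outlier))
    modern_samples <- modern_samples[!as.logical(modern_samples$outlier), ,
                                     drop = FALSE]
  ms <- modern_samples[order(modern_samples$age), , drop = FALSE]
  step <- stats::median(diff(pre_industrial$age))
  b <- max(ms$age)                      # oldest modern sample = junction
  if (min(pre_industrial$age) - b > step + 1e-9)
    stop("gap between modern samples and the pre-industrial curve exceeds one grid step")
  mgrid <- seq(min(ms$age), b, by = step)
  if (max(mgrid) < b - 1e-9) mgrid <- c(mgrid, b)
  f <- splinefun(ms$age, ave_dup(ms$age, ms$value), method = "natural")
  mmean <- f(mgrid)
  msig <- if (!is.null(ms$sigma))
    approx(ms$age, ms$sigma, xout = mgrid, rule = 2)$y else rep(0, length(mgrid))
  keep <- pre_industrial$age > b + 1e-9
  pre <- pre_industrial[keep, , drop = FALSE]
  # cross-fade: blend the youngest retained pre-industrial point toward the
  # modern fit if it lies within one grid step of the junction
  if (nrow(pre) > 0 && pre$age[1] - b <= step + 1e-9) {
    w <- (pre$age[1] - b) / step        # 0 at junction -> all modern
    pm <- f(pre$age[1])
    pre$mean[1] <- w * pre$mean[1] + (1 - w) * pm
  }
  out <- spline_curve(c(mgrid, pre$age), c(mmean, pre$mean),
                      c(msig, pre$sigma),
                      cutoff_yr = attr(pre_industrial, "cutoff_yr"),
                      n_rep = attr(pre_industrial, "n_rep"),
                      perturb = attr(pre_industrial, "perturb"),
                      seed = attr(pre_industrial, "seed"))
  attr(out, "junction_kyr") <- b
  out
}

#' Forward-model a plant d13C curve from atmospheric curves
#'
#' Applies a fractionation model pointwise to CO2 and d13C_CO2 curves that
#' share an age grid. The curve mean is the model evaluated at the curve
#' means; the 1-sigma uncertainty is propagated by Monte Carlo, drawing the
#' two inputs independently from their pointwise normal errors.
#'
#' @param model a [fractionation_model()] (or name).
#' @param pco2_curve,d13c_curve [spline_curve()] objects on a common grid.
#' @param n_rep Monte Carlo replicates for error propagation (default 1000).
#' @param seed RNG seed for the propagation draws.
#' @return a [spline_curve()] of plant d13C (per mil VPDB).
#' @export
model_curve <- function(model, pco2_curve, d13c_curve, n_rep = 1000,
                        seed = NULL) {
  if (is.character(model)) model <- fractionation_model(model)
  stopifnot(inherits(pco2_curve, "spline_curve"),
            inherits(d13c_curve, "spline_curve"))
  if (nrow(pco2_curve) != nrow(d13c_curve) ||
      max(abs(pco2_curve$age - d13c_curve$age)) > 1e-9)
    stop("pco2_curve and d13c_curve must share the same age grid")
  m <- predict_delta_p(model, pco2_curve$mean, d13c_curve$mean)
  n <- nrow(pco2_curve)
  s <- if (all(pco2_curve$sigma == 0) && all(d13c_curve$sigma == 0)) {
    rep(0, n)
  } else {
    draws <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
      p <- pmax(pco2_curve$mean + rnorm(n, 0, pco2_curve$sigma), 1e-6)
      d <- d13c_curve$mean + rnorm(n, 0, d13c_curve$sigma)
      suppressWarnings(predict_delta_p(model, p, d))
    }, numeric(n)))
    apply(draws, 1L, sd)
  }
  spline_curve(pco2_curve$age, m, s, model = model$name, n_rep = n_rep,
               seed = seed)
}

#' Expanded uncertainty for model plant-d13C curves
#'
#' Combines, in quadrature, the propagated ice-core curve uncertainty with
#' the 1-sigma spread of the modern global plant d13C distribution
#' (1.62 per mil), giving a conservative envelope for the plausible range of
#' C3 plant values under a model.
#'
#' @param curve_sigma propagated curve 1-sigma, per mil (vectorised).
#' @param modern_spread 1-sigma spread of modern plant d13C, per mil
#'   (default 1.62).
#' @return expanded 1-sigma, per mil.
#' @export
expanded_uncertainty <- function(curve_sigma, modern_spread = 1.62) {
  if (any(curve_sigma < 0) || any(modern_spread < 0))
    stop("uncertainties must be >= 0")
  sqrt(modern_spread^2 + curve_sigma^2)
}

#' Detect high-amplitude episodes in a curve
#'
#' Finds maximal contiguous age intervals over which the curve changes
#' faster than `rate_min` (centred finite differences; one-sided at the
#' grid ends) and by at least `amp_min` in total. Grid points younger than
#' `exclude_after` (the recent anthropogenic era) are removed before
#' detection. Episodes are reported oldest first.
#'
#' @param curve a [spline_curve()].
#' @param amp_min minimum total change over the interval, per mil
#'   (default 1.0).
#' @param rate_min minimum |local rate|, per mil per kyr (default 0.25).
#' @param exclude_after ages younger than this (kyr BP) are excluded
#'   (default 0.2, i.e. the industrial era).
#' @return data frame with columns `start` (older bound, kyr BP), `end`
#'   (younger bound), `amplitude` (per mil, > 0), `mean_rate` (per mil/kyr);
#'   zero rows when nothing qualifies.
#' @export
detect_episodes <- function(curve, amp_min = 1.0, rate_min = 0.25,
                            exclude_after = 0.2) {
  stopifnot(inherits(curve, "spline_curve"))
  cv <- curve[curve$age >= exclude_after, , drop = FALSE]
  n <- nrow(cv)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      amplitude = numeric(0), mean_rate = numeric(0))
  if (n < 3L) return(empty)
  a <- cv$age; v <- cv$mean
  rate <- numeric(n)
  rate[1] <- (v[2] - v[1]) / (a[2] - a[1])
  rate[n] <- (v[n] - v[n - 1]) / (a[n] - a[n - 1])
  mid <- 2:(n - 1)
  rate[mid] <- (v[mid + 1] - v[mid - 1]) / (a[mid + 1] - a[mid - 1])
  fast <- abs(rate) >= rate_min
  if (!any(fast)) return(empty)
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i1 <- starts[j]; i2 <- ends[j]
    amp <- abs(v[i2] - v[i1])
    if (i2 > i1 && amp >= amp_min) {
      dur <- a[i2] - a[i1]
      out <- rbind(out, data.frame(start = a[i2], end = a[i1],
                                   amplitude = amp, mean_rate = amp / dur))
    }
  }
  out[order(-out$start), , drop = FALSE]
}
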