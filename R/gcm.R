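#' Isotopic effect of a precipitation change
#'
#' Converts a change in mean annual precipitation between the Last Glacial
#' Maximum and the mid-Holocene into its contribution to the change in
#' plant d13C, through the logarithmic MAP regression:
#' `-5.6 * (log10(map_midh + 300) - log10(map_lgm + 300))`.
#'
#' The value is the MAP contribution to the (Holocene minus pre-glacial)
#' difference of d13C means: it is *negative* when the Holocene is wetter
#' than the LGM (wetter conditions lower plant d13C), and antisymmetric
#' under swapping the two states. Note the sign convention is fixed by the
#' physical direction of the effect, not by the order the two epochs are
#' written in.
#'
#' @param map_lgm MAP at the LGM (21 kyr BP), mm/yr (>= 0).
#' @param map_midh MAP at the mid-Holocene (6 kyr BP), mm/yr (>= 0).
#' @return MAP contribution to the deglacial d13C shift, per mil.
#' @examples
#' d13c_map_change(map_lgm = 500, map_midh = 1000)  # wetting: negative
#' @export
d13c_map_change <- function(map_lgm, map_midh) {
  if (any(map_lgm < 0) || any(map_midh < 0)) stop("MAP must be >= 0")
  -5.6 * (log10(map_midh + 300) - log10(map_lgm + 300))
}

#' Multi-model ensemble MAP effect at one site
#'
#' Computes the per-model isotopic MAP contribution at a site and summarises
#' it as the ensemble mean with inter-model 1-sigma spread. A single model
#' gives no spread estimate and is an error.
#'
#' @param pairs data frame for one site with columns `model`,
#'   `map_lgm_mm`, `map_midh_mm` (one row per climate model).
#' @return list of class `"map_effect"` with `mean`, `sigma`, `n_models`.
#' @export
ensemble_effect <- function(pairs) {
  stopifnot_cols(pairs, c("map_lgm_mm", "map_midh_mm"), "pairs")
  if (nrow(pairs) < 2L)
    stop("need >= 2 ensemble members for an inter-model spread")
  eff <- d13c_map_change(pairs$map_lgm_mm, pairs$map_midh_mm)
  structure(list(mean = mean(eff), sigma = sd(eff), n_models = nrow(pairs)),
            class = "map_effect")
}

#' @export
print.map_effect <- function(x, ...) {
  cat(sprintf("<map_effect> %.3g +/- %.3g per mil (inter-model 1-sigma, %d models",
              x$mean, x$sigma, x$n_models))
  if (!is.null(x$wetter_fraction))
    cat(sprintf("; %.0f%% of records at sites predicted wetter",
                100 * x$wetter_fraction))
  cat(")\n")
  invisible(x)
}

#' Per-site ensemble MAP effects
#'
#' @param gcm data frame with columns `model`, `site_id`, `map_lgm_mm`,
#'   `map_midh_mm` for all sites.
#' @return data frame with one row per site: `site_id`, `mean`, `sigma`,
#'   `n_models`, `wetter` (logical: ensemble-mean mid-Holocene MAP exceeds
#'   LGM MAP).
#' @export
site_ensemble_effects <- function(gcm) {
  stopifnot_cols(gcm, c("site_id", "map_lgm_mm", "map_midh_mm"), "gcm")
  parts <- split(gcm, gcm$site_id)
  out <- do.call(rbind, lapply(parts, function(p) {
    e <- ensemble_effect(p)
    data.frame(site_id = p$site_id[1], mean = e$mean, sigma = e$sigma,
               n_models = e$n_models,
               wetter = mean(p$map_midh_mm) > mean(p$map_lgm_mm))
  }))
  rownames(out) <- NULL
  out
}

#' Cohort-level MAP contribution to the deglacial shift
#'
#' Aggregates the ensemble MAP effect over the sites represented in a
#' record compilation. For each ensemble member the cohort value is the
#' weighted mean of its per-site effects — by default weighted by the
#' number of records at each site, so sites contributing more measurements
#' carry proportionally more weight (duplicating a site's rows in the GCM
#' table does not change the result). The reported mean and sigma are the
#' mean and standard deviation of the cohort value across ensemble members
#' (inter-model spread).
#'
#' @param records data frame of records with a `site_id` column.
#' @param gcm ensemble table (`model`, `site_id`, `map_lgm_mm`,
#'   `map_midh_mm`); every record site must be covered.
#' @param weight `"records"` (default) or `"sites"` (each site equal).
#' @return a `"map_effect"` with `mean`, `sigma`, `n_models` and
#'   `wetter_fraction` (record-weighted fraction of sites whose ensemble
#'   mean predicts a wetter mid-Holocene).
#' @export
cohort_map_effect <- function(records, gcm, weight = c("records", "sites")) {
  weight <- match.arg(weight)
  stopifnot_cols(records, "site_id", "records")
  stopifnot_cols(gcm, c("model", "site_id", "map_lgm_mm", "map_midh_mm"),
                 "gcm")
  gcm <- unique(gcm[c("model", "site_id", "map_lgm_mm", "map_midh_mm")])
  sites <- unique(records$site_id)
  missing <- setdiff(sites, unique(gcm$site_id))
  if (length(missing))
    stop("no ensemble coverage for site(s): ",
         paste(missing, collapse = ", "))
  w <- if (weight == "records") table(records$site_id)[as.character(sites)]
       else setNames(rep(1, length(sites)), sites)
  w <- as.numeric(w)
  per_model <- vapply(split(gcm, gcm$model), function(g) {
    eff <- d13c_map_change(g$map_lgm_mm, g$map_midh_mm)
    names(eff) <- g$site_id
    weighted.mean(eff[as.character(sites)], w)
  }, numeric(1))
  se <- site_ensemble_effects(gcm[gcm$site_id %in% sites, , drop = FALSE])
  wet <- se$wetter[match(sites, se$site_id)]
  structure(list(mean = mean(per_model), sigma = sd(per_model),
                 n_models = length(per_model),
                 wetter_fraction = weighted.mean(wet, w)),
            class = "map_effect")
}
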