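#' Tissue-offset conversions to plant-equivalent d13C
#'
#' Herbivore bone collagen is enriched relative to the plant diet by the
#' collagen-diet enrichment factor (5.1 per mil from controlled-feeding
#' studies); wood alpha-cellulose is enriched relative to bulk leaf tissue
#' by about 1 per mil. Both conversions subtract the offset, bringing the
#' two archives onto a common bulk-leaf (diet) scale, so that at equal
#' diets collagen minus cellulose cohort means differ by about 4.1 per mil
#' before conversion and agree after.
#'
#' @param d13c measured d13C, per mil VPDB.
#' @param eps collagen-diet enrichment, per mil (default 5.1).
#' @param offset cellulose - bulk-leaf offset, per mil (default 1.0).
#' @return plant-equivalent (bulk leaf) d13C, per mil VPDB.
#' @export
collagen_to_plant <- function(d13c, eps = 5.1) {
  stopifnot(eps >= 0)
  d13c - eps
}

#' @rdname collagen_to_plant
#' @export
cellulose_to_leaf <- function(d13c, offset = 1.0) {
  stopifnot(offset >= 0)
  d13c - offset
}

#' @rdname collagen_to_plant
#' @param archive character vector, `"collagen"` or `"cellulose"`, recycled
#'   against `d13c`.
#' @export
plant_equivalent <- function(d13c, archive, eps = 5.1, offset = 1.0) {
  archive <- rep_len(tolower(archive), length(d13c))
  bad <- !archive %in% c("collagen", "cellulose")
  if (any(bad)) stop("unknown archive: ", paste(unique(archive[bad]), collapse = ", "))
  ifelse(archive == "collagen", d13c - eps, d13c - offset)
}

#' Curate a proxy-record compilation
#'
#' Applies the standard record-selection rules: keep only sites with
#' predominantly C3 vegetation, drop lichen-consuming species (lichens are
#' not C3 vascular plants and carry anomalous d13C), restrict to an age
#' window, and exclude the industrial era (after ~1750 CE, i.e. ages
#' younger than 0.2 kyr BP), whose anthropogenic d13C_CO2 decline would
#' contaminate pre-industrial group means. Rules with missing columns are
#' skipped. The number of records removed by each rule is reported via
#' `message()` and stored in the `"removals"` attribute.
#'
#' @param records data frame of proxy records (columns per
#'   [read_records()]; only the columns a rule needs are required).
#' @param min_c3_fraction minimum site C3 vegetation fraction
#'   (default 0.9); `NULL` disables.
#' @param exclude_lichen drop records flagged `lichen_feeder` (default TRUE).
#' @param age_range optional `c(min, max)` age window in kyr BP.
#' @param exclude_industrial drop ages younger than
#'   `industrial_cutoff_kyr` (default TRUE).
#' @param industrial_cutoff_kyr industrial-era cutoff, kyr BP (default 0.2).
#' @return the curated subset, with a `"removals"` attribute (named counts).
#' @export
filter_records <- function(records, min_c3_fraction = 0.9,
                           exclude_lichen = TRUE, age_range = NULL,
                           exclude_industrial = TRUE,
                           industrial_cutoff_kyr = 0.2) {
  removals <- integer(0)
  drop_rule <- function(df, keep, rule) {
    keep[is.na(keep)] <- TRUE
    removals[rule] <<- sum(!keep)
    df[keep, , drop = FALSE]
  }
  out <- records
  if (!is.null(min_c3_fraction) && !is.null(out$c3_fraction))
    out <- drop_rule(out, out$c3_fraction >= min_c3_fraction, "c3_fraction")
  if (isTRUE(exclude_lichen) && !is.null(out$lichen_feeder))
    out <- drop_rule(out, !as.logical(out$lichen_feeder), "lichen_feeder")
  if (!is.null(age_range) && !is.null(out$age))
    out <- drop_rule(out, out$age >= age_range[1] & out$age <= age_range[2],
                     "age_range")
  if (isTRUE(exclude_industrial) && !is.null(out$age))
    out <- drop_rule(out, out$age >= industrial_cutoff_kyr, "industrial")
  if (length(removals) && any(removals > 0))
    message("filter_records removed: ",
            paste(sprintf("%s=%d", names(removals), removals), collapse = ", "))
  if (nrow(out) == 0L) warning("no records survive the filters")
  attr(out, "removals") <- removals
  out
}

#' Standard deglacial comparison windows
#'
#' The pre-deglacial group is everything older than 20 kyr BP and the
#' post-deglacial (Holocene) group everything younger than 10 kyr BP but
#' older than the industrial cutoff.
#'
#' @param industrial_cutoff_kyr young limit of the Holocene window,
#'   kyr BP (default 0.2).
#' @return named list of `c(min, max)` age windows (kyr BP).
#' @export
deglacial_windows <- function(industrial_cutoff_kyr = 0.2) {
  list(pre = c(20, Inf), post = c(industrial_cutoff_kyr, 10))
}

#' Per-window group statistics
#'
#' Unweighted mean, standard deviation, standard error and count of a
#' record column within each age window. Windows are half-open on the young
#' side: a record belongs to window `c(lo, hi)` when `lo <= age < hi` for
#' finite `hi`, and `age > lo` when `hi` is infinite.
#'
#' @param records data frame with an `age` column (kyr BP).
#' @param value name of the value column (default `"d13c_adj"`).
#' @param windows named list of `c(min, max)` windows,
#'   default [deglacial_windows()].
#' @return data frame with columns `window`, `n`, `mean`, `sd`, `se`.
#' @export
group_means <- function(records, value = "d13c_adj",
                        windows = deglacial_windows()) {
  stopifnot_cols(records, c("age", value), "records")
  rows <- lapply(names(windows), function(w) {
    rg <- windows[[w]]
    inw <- if (is.finite(rg[2])) records$age >= rg[1] & records$age < rg[2]
           else records$age > rg[1]
    x <- records[[value]][inw]
    x <- x[is.finite(x)]
    if (length(x) == 0L)
      stop(sprintf("window '%s' [%s, %s] kyr contains no records", w,
                   format(rg[1]), format(rg[2])))
    data.frame(window = w, n = length(x), mean = mean(x), sd = sd(x),
               se = sd(x) / sqrt(length(x)))
  })
  do.call(rbind, rows)
}

#' Read a proxy-record table from CSV
#'
#' Expected columns: `id, archive, taxon_group, age_kyr_bp, age_sigma_kyr,
#' d13c, lat, lon` and optionally `altitude_m, map_mm, c3_fraction,
#' lichen_feeder`. Column `age_kyr_bp` is renamed to `age`.
#'
#' @param path CSV file path.
#' @return data frame of proxy records.
#' @export
read_records <- function(path) {
  df <- read.csv(path)
  if ("age_kyr_bp" %in% names(df) && !"age" %in% names(df))
    names(df)[names(df) == "age_kyr_bp"] <- "age"
  stopifnot_cols(df, c("id", "archive", "age", "d13c", "lat", "lon"),
                 "record file")
  df
}
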