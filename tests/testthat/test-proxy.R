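test_that("tissue-offset conversions shift and round-trip", {
  expect_equal(collagen_to_plant(-21.78), -26.88)
  expect_equal(collagen_to_plant(-21.78, eps = 0), -21.78)
  expect_equal(cellulose_to_leaf(-25.0), -26.0)
  expect_equal(cellulose_to_leaf(-25.0, offset = 0), -25.0)
  x <- c(-20.1, -23.4)
  expect_equal(collagen_to_plant(x) + 5.1, x)
  expect_equal(plant_equivalent(c(-21, -25), c("collagen", "cellulose")),
               c(-26.1, -26))
  expect_error(plant_equivalent(-21, "enamel"), "unknown archive")
})

test_that("co-generated archives agree after conversion to leaf scale", {
  sc <- sim_scenario(scenario_config(seed = 12, n_records = 600))
  rec <- sc$records
  raw_gap <- mean(rec$d13c[rec$archive == "collagen"]) -
             mean(rec$d13c[rec$archive == "cellulose"])
  expect_equal(raw_gap, 5.1 - 1.0, tolerance = 0.35)
  pe <- plant_equivalent(rec$d13c, rec$archive)
  expect_equal(mean(pe[rec$archive == "collagen"]) -
               mean(pe[rec$archive == "cellulose"]), 0, tolerance = 0.35)
})

toy_records <- function() {
  data.frame(id = paste0("r", 1:5),
             archive = "collagen",
             age = c(25, 8, 3, 0.1, 22),
             d13c = -21,
             c3_fraction = c(1, 0.8, 1, 1, 0.99),
             lichen_feeder = c(FALSE, FALSE, TRUE, FALSE, FALSE))
}

test_that("curation rules drop the right records and log removals", {
  rec <- toy_records()
  suppressMessages({
    kept <- filter_records(rec, exclude_industrial = FALSE)
  })
  expect_equal(nrow(kept), 3)                       # C3 filter + lichen
  expect_equal(attr(kept, "removals")[["c3_fraction"]], 1)
  expect_equal(attr(kept, "removals")[["lichen_feeder"]], 1)
  suppressMessages({
    all_rules <- filter_records(rec)
  })
  expect_equal(nrow(all_rules), 2)                  # industrial era too
  expect_false(any(all_rules$age < 0.2))
  # no active rules: identity
  ident <- filter_records(rec, min_c3_fraction = NULL,
                          exclude_lichen = FALSE, exclude_industrial = FALSE)
  expect_equal(nrow(ident), 5)
  expect_warning(suppressMessages(
    filter_records(rec, min_c3_fraction = 1.1)), "no records")
})

test_that("curation is idempotent and order-independent", {
  rec <- toy_records()
  suppressMessages({
    once <- filter_records(rec)
    twice <- filter_records(once)
    other <- filter_records(filter_records(rec, min_c3_fraction = NULL),
                            exclude_lichen = FALSE)
  })
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  expect_setequal(other$id, once$id)
})

test_that("group means and windows behave", {
  rec <- data.frame(age = c(25, 26, 27, 3, 4, 5), d13c_adj = -22)
  gm <- group_means(rec)
  expect_equal(gm$mean, c(-22, -22))
  expect_equal(gm$sd, c(0, 0))
  expect_equal(gm$n, c(3, 3))
  # industrial-era records never enter the young window
  rec2 <- rbind(rec, data.frame(age = 0.05, d13c_adj = 99))
  expect_equal(group_means(rec2)$mean[2], -22)
  expect_error(group_means(data.frame(age = 15, d13c_adj = -22)),
               "no records")
})

test_that("an injected two-group difference is recovered across seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    d <- -0.9
    rec <- data.frame(age = c(runif(60, 21, 30), runif(60, 1, 9)),
                      d13c_adj = c(rnorm(60, -21, 0.8), rnorm(60, -21 + d, 0.8)))
    gm <- group_means(rec)
    est <- gm$mean[gm$window == "post"] - gm$mean[gm$window == "pre"]
    se <- sqrt(sum(gm$se^2))
    hits <- hits + (abs(est - d) <= 2 * se)
  }
  expect_gte(hits, 18L)
})

test_that("record CSV reader renames and validates", {
  sc <- sim_scenario(quick_cfg(seed = 6))
  f <- tempfile(fileext = ".csv")
  out <- sc$records
  names(out)[names(out) == "age"] <- "age_kyr_bp"
  write.csv(out, f, row.names = FALSE)
  rec <- read_records(f)
  expect_true("age" %in% names(rec))
  expect_equal(nrow(rec), nrow(sc$records))
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1), bad, row.names = FALSE)
  expect_error(read_records(bad), "missing")
})
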