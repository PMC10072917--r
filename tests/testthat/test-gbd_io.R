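test_that("default schemes carry the 21-cause / 3-group hierarchy and GBD ages", {
  cs <- gbd_cause_scheme()
  expect_equal(cs$k, 21L)
  sizes <- table(cs$level1)
  expect_setequal(as.integer(sizes), c(7L, 11L, 3L))
  expect_equal(length(unique(cs$level1)), 3L)

  as_ <- gbd_age_scheme()
  expect_equal(as_$n_groups, 21L)
  expect_equal(as_$lower[1:3], c(0, 1, 5))
  expect_true(is.infinite(as_$width[as_$n_groups]))
  expect_equal(as_$labels[c(1, 2, 21)], c("<1", "1 to 4", "95 plus"))
})

test_that("age-label matching accepts both GBD dialect and shorthand", {
  as_ <- gbd_age_scheme()
  expect_equal(match_age_labels(c("<1", "1 to 4", "5 to 9", "95 plus"), as_),
               c(1L, 2L, 3L, 21L))
  expect_equal(match_age_labels(c("0-1", "1-5", "5-9", "95+"), as_),
               c(1L, 2L, 3L, 21L))
  expect_equal(match_age_labels("10 to 14 years", as_), 4L)
  expect_error(match_age_labels("3 to 7", as_), "unknown age-group label")
})

test_that("well-formed toy CSV reads to a complete panel", {
  cs <- cause_scheme(c("a", "b", "c"), c("g1", "g1", "g2"))
  as_ <- age_scheme(c(0, 50))
  df <- toy_panel_df(cs = cs, as_ = as_, rate = c(0.01, 0.02, 0.03,
                                                  0.04, 0.05, 0.06))
  df$age <- as_$labels[df$age_index]
  names(df)[names(df) == "rate"] <- "val"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[, c("location", "region", "sex", "year", "age",
                          "cause", "val", "lower", "upper", "population")],
                   path, row.names = FALSE)
  p <- read_panel(path, cs, as_)
  expect_s3_class(p, "mortality_panel")
  expect_equal(nrow(p), 6L)   # 2 ages x 3 causes per slice
})

test_that("a missing grid cell is rejected with the cell named", {
  cs <- toy_cause_scheme(); as_ <- toy_age_scheme()
  df <- toy_panel_df(cs = cs, as_ = as_)
  drop <- df$age_index == 3L & df$cause == "injury"
  expect_error(mortality_panel(df[!drop, ], cs, as_),
               "missing cells.*3 \\| injury")
  dup <- rbind(df, df[1L, ])
  expect_error(mortality_panel(dup, cs, as_), "duplicate")
})

test_that("uncertainty bounds are validated", {
  cs <- toy_cause_scheme(); as_ <- toy_age_scheme()
  df <- toy_panel_df(cs = cs, as_ = as_)
  df$lower[5L] <- df$rate[5L] * 2
  expect_error(mortality_panel(df, cs, as_), "lower <= rate <= upper")
  df2 <- toy_panel_df(cs = cs, as_ = as_)
  df2$rate[2L] <- -0.1
  expect_error(mortality_panel(df2, cs, as_), "non-negative")
})

test_that("write_panel / read_panel round-trips a panel", {
  set.seed(41)
  cs <- toy_cause_scheme(); as_ <- toy_age_scheme()
  df <- toy_panel_df(locations = c("A", "B"), sexes = c("female", "male"),
                     years = c(2000L, 2001L), cs = cs, as_ = as_,
                     rate = stats::runif(84, 1e-5, 0.3))
  p <- mortality_panel(df, cs, as_)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  p2 <- read_panel(path, cs, as_)
  ord <- function(x) x[order(x$location, x$sex, x$year, x$age_index,
                             x$cause), ]
  a <- ord(as.data.frame(p)); b <- ord(as.data.frame(p2))
  expect_identical(a[, c("location", "region", "sex", "year", "age_index",
                         "cause")],
                   b[, c("location", "region", "sex", "year", "age_index",
                         "cause")])
  for (cl in c("rate", "lower", "upper", "population"))
    expect_equal(a[[cl]], b[[cl]], tolerance = 1e-12)
})

test_that("death counts convert to rates on read", {
  cs <- toy_cause_scheme(); as_ <- toy_age_scheme()
  df <- toy_panel_df(cs = cs, as_ = as_, rate = 500, population = 1e5)
  df$age <- as_$labels[df$age_index]
  names(df)[names(df) == "rate"] <- "val"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  p <- read_panel(path, cs, as_, measure = "count")
  expect_equal(unique(p$rate), 500 / 1e5)
})

test_that("results tables have stable shapes, including empty inputs", {
  out <- withr::local_tempdir()
  levels <- expand.grid(region = c("r1", "r2"), sex = c("f", "m"),
                        year = c(1990L, 2019L), stringsAsFactors = FALSE)
  levels$F <- 0.8; levels$lower <- 0.79; levels$upper <- 0.81
  levels$diff <- NA_real_; levels$significant <- NA
  write_results_tables(list(levels = levels), out)
  got <- utils::read.csv(file.path(out, "levels.csv"))
  expect_equal(nrow(got), 8L)   # 2 regions x 2 sexes x 2 years
  expect_equal(names(got), c("region", "sex", "year", "F", "lower",
                             "upper", "diff", "significant"))

  write_results_tables(list(levels = NULL,
                            decomposition = data.frame(),
                            curves = data.frame()), out)
  for (f in c("levels.csv", "decomposition.csv", "loess_curves.csv")) {
    tab <- utils::read.csv(file.path(out, f))
    expect_equal(nrow(tab), 0L)
    expect_gt(ncol(tab), 4L)
  }
})

test_that("a decomposition table covers the full cause x age grid", {
  cs <- gbd_cause_scheme(); as_ <- gbd_age_scheme()
  set.seed(7)
  r1 <- matrix(stats::runif(21 * 21, 1e-4, 0.05), 21, 21)
  dec <- decompose_F_change(r1, r1 * 1.05, as_, cs, n_steps = 1L)
  tab <- decomposition_table(dec, region = "r", sex = "f")
  expect_equal(nrow(tab), 21L * 21L)
  expect_setequal(unique(tab$cause), cs$causes)
  expect_setequal(unique(tab$age_lower), as_$lower)
})
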