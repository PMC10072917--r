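#' Read a GBD-results-style CSV extract into a mortality panel
#'
#' Reads long-format CSV as distributed by the GBD results tool: one row per
#' (location, sex, year, age group, cause) with a point estimate and 95%
#' uncertainty bounds. Age-group labels in either the GBD dialect
#' (`"<1"`, `"1 to 4"`, `"95 plus"`) or compact shorthand (`"0-1"`, `"95+"`)
#' are accepted. The canonical internal unit is deaths per person-year; when
#' `measure = "count"` the value columns are death counts and are divided by
#' the population column on read.
#'
#' @param path CSV file path.
#' @param cause_scheme a [cause_scheme()].
#' @param age_scheme an [age_scheme()].
#' @param measure `"rate"` (deaths per person-year, default) or `"count"`
#'   (death counts, converted to rates using `population`).
#' @param cols named list mapping panel fields to CSV column names; defaults
#'   to `location`, `region`, `sex`, `year`, `age`, `cause`, `val`, `lower`,
#'   `upper`, `population`. A missing `region` column defaults to the
#'   location label.
#' @param region_lookup optional named character vector mapping location to
#'   region, overriding any region column.
#' @return A validated [mortality_panel()].
#' @export
read_panel <- function(path, cause_scheme, age_scheme,
                       measure = c("rate", "count"),
                       cols = list(), region_lookup = NULL) {
  measure <- match.arg(measure)
  cmap <- utils::modifyList(
    list(location = "location", region = "region", sex = "sex",
         year = "year", age = "age", cause = "cause", val = "val",
         lower = "lower", upper = "upper", population = "population"),
    cols)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- setdiff(unlist(cmap[c("location", "sex", "year", "age", "cause",
                                "val", "lower", "upper", "population")]),
                  names(raw))
  if (length(need))
    stop("CSV is missing column(s): ", paste(need, collapse = ", "))

  df <- data.frame(
    location = as.character(raw[[cmap$location]]),
    region = if (cmap$region %in% names(raw))
      as.character(raw[[cmap$region]]) else as.character(raw[[cmap$location]]),
    sex = as.character(raw[[cmap$sex]]),
    year = as.integer(raw[[cmap$year]]),
    age_index = match_age_labels(raw[[cmap$age]], age_scheme),
    cause = as.character(raw[[cmap$cause]]),
    rate = as.numeric(raw[[cmap$val]]),
    lower = as.numeric(raw[[cmap$lower]]),
    upper = as.numeric(raw[[cmap$upper]]),
    population = as.numeric(raw[[cmap$population]]),
    stringsAsFactors = FALSE)

  if (!is.null(region_lookup)) {
    reg <- region_lookup[df$location]
    if (anyNA(reg))
      stop("region_lookup is missing location(s): ",
           paste(unique(df$location[is.na(reg)]), collapse = ", "))
    df$region <- unname(reg)
  }
  if (measure == "count") {
    if (any(df$population <= 0))
      stop("count-to-rate conversion needs positive population in every cell")
    df$rate <- df$rate / df$population
    df$lower <- df$lower / df$population
    df$upper <- df$upper / df$population
  }
  mortality_panel(df, cause_scheme, age_scheme)
}

#' Write a mortality panel as a GBD-dialect CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p))` reproduces `p`
#' (labels exactly; rates to full double precision).
#'
#' @param panel a [mortality_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  as <- attr(panel, "age_scheme")
  out <- data.frame(
    location = panel$location, region = panel$region, sex = panel$sex,
    year = panel$year, age = as$labels[panel$age_index],
    cause = panel$cause,
    val = format(panel$rate, digits = 17, scientific = TRUE, trim = TRUE),
    lower = format(panel$lower, digits = 17, scientific = TRUE, trim = TRUE),
    upper = format(panel$upper, digits = 17, scientific = TRUE, trim = TRUE),
    population = format(panel$population, digits = 17, scientific = TRUE,
                        trim = TRUE),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the pipeline's result tables to CSV
#'
#' Writes up to three plain CSV tables into `out_dir`: `levels.csv`
#' (region, sex, year, F, lower, upper, diff, significant),
#' `decomposition.csv` (region, sex, cause, age_lower, contribution) and
#' `loess_curves.csv` (predictor, sex, year, x, fitted, span, degree).
#' Empty inputs produce header-only files.
#'
#' @param results list with any of `levels`, `decomposition`, `curves`
#'   data.frames as produced by [run_levels()], [run_decomposition()] and
#'   [run_association()].
#' @param out_dir output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_results_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  schema <- list(
    levels = c("region", "sex", "year", "F", "lower", "upper", "diff",
               "significant"),
    decomposition = c("region", "sex", "cause", "age_lower", "contribution"),
    curves = c("predictor", "sex", "year", "x", "fitted", "span", "degree"))
  files <- c(levels = "levels.csv", decomposition = "decomposition.csv",
             curves = "loess_curves.csv")
  for (nm in names(schema)) {
    if (!nm %in% names(results)) next
    tab <- results[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) {
      tab <- as.data.frame(stats::setNames(
        rep(list(logical(0)), length(schema[[nm]])), schema[[nm]]))
    } else {
      miss <- setdiff(schema[[nm]], names(tab))
      if (length(miss))
        stop("results$", nm, " is missing column(s): ",
             paste(miss, collapse = ", "))
      tab <- tab[, schema[[nm]]]
    }
    f <- file.path(out_dir, files[[nm]])
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
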