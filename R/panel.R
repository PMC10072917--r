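#' Construct and validate a mortality panel
#'
#' The universal input container: one record per (location, sex, year,
#' age group, cause) holding a cause-specific mortality rate (deaths per
#' person-year), its 95% uncertainty bounds and the population exposed.
#' Each (location, sex, year) slice must cover the full age x cause grid.
#'
#' @param df data.frame with columns `location`, `region`, `sex`, `year`,
#'   `age_index` (integer into the age scheme), `cause`, `rate`, `lower`,
#'   `upper`, `population`.
#' @param cause_scheme a [cause_scheme()].
#' @param age_scheme an [age_scheme()].
#' @return The validated data.frame with class `mortality_panel` and the two
#'   schemes attached as attributes.
#' @export
mortality_panel <- function(df, cause_scheme, age_scheme) {
  needed <- c("location", "region", "sex", "year", "age_index", "cause",
              "rate", "lower", "upper", "population")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, needed]
  df$age_index <- as.integer(df$age_index)

  bad_cause <- setdiff(unique(df$cause), cause_scheme$causes)
  if (length(bad_cause))
    stop("unknown cause(s): ", paste(bad_cause, collapse = ", "))
  if (any(df$age_index < 1L | df$age_index > age_scheme$n_groups))
    stop("age_index out of range for the age scheme")

  num <- c("rate", "lower", "upper", "population")
  for (cl in num) {
    if (!is.numeric(df[[cl]]) || anyNA(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop("column `", cl, "` must be finite numeric with no NA")
    if (any(df[[cl]] < 0)) stop("column `", cl, "` must be non-negative")
  }
  bad <- df$lower > df$rate + 1e-12 | df$rate > df$upper + 1e-12
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("uncertainty bounds must satisfy lower <= rate <= upper; first ",
         "violation at (", df$location[i], ", ", df$sex[i], ", ",
         df$year[i], ", age_index ", df$age_index[i], ", ", df$cause[i], ")")
  }

  check_grid_complete(df, cause_scheme, age_scheme)

  structure(df,
            class = c("mortality_panel", "data.frame"),
            cause_scheme = cause_scheme,
            age_scheme = age_scheme)
}

# every (location, sex, year) slice must contain each (age, cause) cell once
check_grid_complete <- function(df, cause_scheme, age_scheme) {
  slice <- interaction(df$location, df$sex, df$year, drop = TRUE, sep = " | ")
  cell <- paste(df$age_index, df$cause, sep = " | ")
  full <- as.vector(outer(seq_len(age_scheme$n_groups), cause_scheme$causes,
                          paste, sep = " | "))
  gaps <- character(0)
  for (s in levels(slice)) {
    have <- cell[slice == s]
    if (anyDuplicated(have))
      stop("duplicate (age, cause) cells in slice (", s, ")")
    missing <- setdiff(full, have)
    if (length(missing))
      gaps <- c(gaps, paste0("(", s, ", age_index | cause = ", missing, ")"))
  }
  if (length(gaps))
    stop("incomplete age x cause grid; missing cells:\n  ",
         paste(utils::head(gaps, 20L), collapse = "\n  "),
         if (length(gaps) > 20L) paste0("\n  ... and ", length(gaps) - 20L,
                                        " more") else "")
  invisible(TRUE)
}

#' @export
print.mortality_panel <- function(x, ...) {
  cs <- attr(x, "cause_scheme"); as <- attr(x, "age_scheme")
  cat("<mortality_panel> ", nrow(x), " records: ",
      length(unique(x$location)), " location(s), ",
      length(unique(x$sex)), " sex(es), ",
      length(unique(x$year)), " year(s); ",
      as$n_groups, " age groups x ", cs$k, " causes\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Extract the age x cause rate matrix of one panel slice
#'
#' @param panel a [mortality_panel()].
#' @param location,sex,year slice selectors.
#' @param what which column to extract (`"rate"`, `"lower"` or `"upper"`).
#' @return numeric matrix (age groups x causes), dimnames from the schemes.
#' @export
slice_rates <- function(panel, location, sex, year, what = "rate") {
  cs <- attr(panel, "cause_scheme"); as <- attr(panel, "age_scheme")
  sel <- panel$location == location & panel$sex == sex & panel$year == year
  if (!any(sel))
    stop("no records for slice (", location, ", ", sex, ", ", year, ")")
  sub <- panel[sel, ]
  m <- matrix(0, as$n_groups, cs$k,
              dimnames = list(as$labels, cs$causes))
  m[cbind(sub$age_index, match(sub$cause, cs$causes))] <- sub[[what]]
  m
}

# age-specific populations of one slice (constant across causes within a cell)
slice_population <- function(panel, location, sex, year) {
  as <- attr(panel, "age_scheme")
  sel <- panel$location == location & panel$sex == sex & panel$year == year
  sub <- panel[sel, ]
  pop <- numeric(as$n_groups)
  pop[sub$age_index] <- sub$population
  pop
}
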