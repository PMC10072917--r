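#' Cause classification scheme
#'
#' A cause scheme is an ordered list of mutually exclusive cause-of-death
#' labels, each nested in one of a small number of broad (level-1) groups.
#' The default scheme, [gbd_cause_scheme()], carries the 21 level-2 causes
#' of the GBD hierarchy nested in its 3 level-1 groups.
#'
#' @param causes character vector of unique cause labels, in display order.
#' @param level1 character vector, same length, giving the level-1 group of
#'   each cause.
#' @return An object of class `cause_scheme`: a list with elements `causes`,
#'   `level1` (named by cause) and `k` (number of causes).
#' @examples
#' sch <- cause_scheme(c("a", "b", "c"), c("g1", "g1", "g2"))
#' sch$k
#' @export
cause_scheme <- function(causes, level1) {
  causes <- as.character(causes)
  level1 <- as.character(level1)
  if (length(causes) < 1L) stop("need at least one cause")
  if (anyDuplicated(causes)) stop("cause labels must be unique")
  if (length(level1) != length(causes))
    stop("`level1` must have one entry per cause")
  if (anyNA(causes) || anyNA(level1)) stop("cause labels must not be NA")
  structure(
    list(causes = causes,
         level1 = stats::setNames(level1, causes),
         k = length(causes)),
    class = "cause_scheme"
  )
}

#' @export
print.cause_scheme <- function(x, ...) {
  cat("<cause_scheme> ", x$k, " causes in ",
      length(unique(x$level1)), " level-1 groups\n", sep = "")
  grp <- split(x$causes, x$level1[x$causes])
  for (g in names(grp)) {
    cat("  ", g, " (", length(grp[[g]]), "): ",
        paste(utils::head(grp[[g]], 3L), collapse = ", "),
        if (length(grp[[g]]) > 3L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Default GBD level-2 cause scheme
#'
#' The 21 level-2 causes of the GBD cause hierarchy, nested in the 3 level-1
#' groups: communicable, maternal, neonatal, and nutritional diseases (7
#' causes); non-communicable diseases (11 causes); injuries (3 causes).
#'
#' @return A [cause_scheme()] with `k = 21`.
#' @export
gbd_cause_scheme <- function() {
  cmnn <- c("HIV/AIDS and sexually transmitted infections",
            "Respiratory infections and tuberculosis",
            "Enteric infections",
            "Neglected tropical diseases and malaria",
            "Other infectious diseases",
            "Maternal and neonatal disorders",
            "Nutritional deficiencies")
  ncd <- c("Neoplasms",
           "Cardiovascular diseases",
           "Chronic respiratory diseases",
           "Digestive diseases",
           "Neurological disorders",
           "Mental disorders",
           "Substance use disorders",
           "Diabetes and kidney diseases",
           "Skin and subcutaneous diseases",
           "Musculoskeletal disorders",
           "Other non-communicable diseases")
  inj <- c("Transport injuries",
           "Unintentional injuries",
           "Self-harm and interpersonal violence")
  cause_scheme(
    causes = c(cmnn, ncd, inj),
    level1 = c(rep("Communicable, maternal, neonatal, and nutritional diseases",
                   length(cmnn)),
               rep("Non-communicable diseases", length(ncd)),
               rep("Injuries", length(inj)))
  )
}

#' Age-group scheme
#'
#' Defines the abridged age grid: ascending lower bounds in years; all
#' intervals are closed except the terminal one, which is open-ended.
#'
#' @param lower_bounds strictly ascending numeric vector of interval lower
#'   bounds in years; the last bound starts the open interval.
#' @return Object of class `age_scheme`: list with `lower` (bounds), `width`
#'   (interval widths, `Inf` for the open terminal interval), `n_groups`,
#'   and `labels` (GBD-dialect labels).
#' @examples
#' as5 <- age_scheme(c(0, 1, seq(5, 95, by = 5)))
#' as5$n_groups
#' @export
age_scheme <- function(lower_bounds) {
  lb <- as.numeric(lower_bounds)
  if (length(lb) < 2L) stop("need at least two age groups")
  if (anyNA(lb) || any(diff(lb) <= 0) || lb[1L] < 0)
    stop("`lower_bounds` must be non-negative and strictly ascending")
  width <- c(diff(lb), Inf)
  structure(
    list(lower = lb, width = width, n_groups = length(lb),
         labels = age_group_labels(lb)),
    class = "age_scheme"
  )
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("<age_scheme> ", x$n_groups, " groups: ",
      paste(utils::head(x$labels, 3L), collapse = ", "),
      ", ..., ", x$labels[x$n_groups], "\n", sep = "")
  invisible(x)
}

#' Default GBD age-group scheme
#'
#' `<1`, `1 to 4`, then 5-year groups up to the open `95 plus` interval
#' (21 groups).
#'
#' @return An [age_scheme()].
#' @export
gbd_age_scheme <- function() {
  age_scheme(c(0, 1, seq(5, 95, by = 5)))
}

age_group_labels <- function(lower) {
  n <- length(lower)
  upper <- c(lower[-1L], NA)
  lab <- character(n)
  for (i in seq_len(n)) {
    if (i == n) {
      lab[i] <- paste(fmt_age(lower[i]), "plus")
    } else if (lower[i] == 0 && upper[i] == 1) {
      lab[i] <- "<1"
    } else {
      lab[i] <- paste(fmt_age(lower[i]), "to", fmt_age(upper[i] - 1))
    }
  }
  lab
}

fmt_age <- function(a) {
  if (a == as.integer(a)) format(as.integer(a)) else format(a)
}

#' Map age-group labels to age-scheme indices
#'
#' Accepts both the GBD export dialect (`"<1"`, `"1 to 4"`, `"95 plus"`,
#' optionally suffixed with `"years"`) and the compact shorthand (`"0-1"`,
#' `"1-5"`, `"5-9"`, `"95+"`). Labels are matched by their lower bound.
#'
#' @param labels character vector of age-group labels.
#' @param scheme an [age_scheme()].
#' @return integer vector of indices into `scheme$lower`.
#' @export
match_age_labels <- function(labels, scheme) {
  lw <- vapply(as.character(labels), age_label_lower, numeric(1))
  idx <- match(lw, scheme$lower)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown age-group label(s): ", paste(bad, collapse = ", "))
  }
  idx
}

age_label_lower <- function(lab) {
  s <- trimws(tolower(lab))
  s <- sub("\\s*years?$", "", s)
  if (grepl("^<", s)) return(0)
  if (grepl("plus$", s)) return(as.numeric(trimws(sub("plus$", "", s))))
  if (grepl("\\+$", s)) return(as.numeric(sub("\\+$", "", s)))
  if (grepl(" to ", s)) return(as.numeric(trimws(strsplit(s, " to ")[[1L]][1L])))
  if (grepl("-", s)) return(as.numeric(strsplit(s, "-")[[1L]][1L]))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse age-group label: ", lab)
  v
}
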