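#' Horiuchi stepwise-replacement decomposition
#'
#' Attributes the change `f(c2) - f(c1)` in a scalar functional of a
#' covariate array to each covariate, by numerically integrating the partial
#' derivatives of `f` along a path from `c1` to `c2`. The path changes each
#' covariate proportionally (geometrically) between its endpoints; cells
#' where either endpoint is zero move linearly (the geometric path is
#' undefined there). The integral uses `n_steps` midpoint central
#' differences; the residual (difference between the summed contributions
#' and the exact change) is then distributed across cells proportionally to
#' the absolute contributions so that additivity is exact.
#'
#' @param f function taking a covariate array shaped like `c1` and returning
#'   a finite scalar.
#' @param c1,c2 numeric arrays (any common shape) of covariates at the two
#'   compared points.
#' @param n_steps number of integration steps (default 20).
#' @return Object of class `horiuchi_decomposition`: list with
#'   `contribution` (array shaped like `c1`, summing exactly to `total`),
#'   `total` (`f(c2) - f(c1)`), `residual` (pre-distribution residual) and
#'   `n_steps`.
#' @examples
#' f <- function(v) v[1] * v[2]
#' h <- horiuchi_decompose(f, c(1, 1), c(2, 3), n_steps = 200)
#' h$contribution  # -> (5 log 2 / log 6, 5 log 3 / log 6)
#' @export
horiuchi_decompose <- function(f, c1, c2, n_steps = 20L) {
  if (!identical(dim(c1), dim(c2)) || length(c1) != length(c2))
    stop("`c1` and `c2` must share the same shape")
  v1 <- as.numeric(c1); v2 <- as.numeric(c2)
  if (anyNA(v1) || anyNA(v2) || any(!is.finite(v1)) || any(!is.finite(v2)) ||
      any(v1 < 0) || any(v2 < 0))
    stop("covariates must be finite and non-negative")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be positive")

  geo <- v1 > 0 & v2 > 0
  ratio <- ifelse(geo, v2 / v1, NA_real_)
  path_at <- function(t) ifelse(geo, v1 * ratio^t, v1 + t * (v2 - v1))

  shape <- function(x) {
    if (!is.null(dim(c1))) array(x, dim = dim(c1), dimnames = dimnames(c1))
    else stats::setNames(x, names(c1))
  }
  eval_f <- function(v, step) {
    val <- f(shape(v))
    if (!is.finite(val))
      stop("functional is non-finite along the path at step ", step)
    val
  }

  ncell <- length(v1)
  contrib <- numeric(ncell)
  for (s in seq_len(n_steps)) {
    lo <- path_at((s - 1) / n_steps)
    hi <- path_at(s / n_steps)
    mid <- path_at((s - 0.5) / n_steps)
    for (j in seq_len(ncell)) {
      if (lo[j] == hi[j]) next
      up <- mid; up[j] <- hi[j]
      dn <- mid; dn[j] <- lo[j]
      contrib[j] <- contrib[j] + (eval_f(up, s) - eval_f(dn, s))
    }
  }

  total <- eval_f(v2, n_steps) - eval_f(v1, 0L)
  residual <- total - sum(contrib)
  ab <- abs(contrib)
  if (sum(ab) > 0) contrib <- contrib + residual * ab / sum(ab)

  structure(list(contribution = shape(contrib), total = total,
                 residual = residual, n_steps = n_steps),
            class = "horiuchi_decomposition")
}

#' @export
print.horiuchi_decomposition <- function(x, ...) {
  cat("<horiuchi_decomposition> total change ",
      format(x$total, digits = 6), " over ", length(x$contribution),
      " covariate(s); n_steps = ", x$n_steps,
      ", residual before distribution ", format(x$residual, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Decompose a change in cause-of-death diversity into cause x age cells
#'
#' Applies [horiuchi_decompose()] to the fractionalization index viewed as a
#' functional of the full cause-by-age mortality surface: the covariates are
#' the cause-age-specific rates `m[x, c]`, the all-cause schedule is their
#' row sum, and F is computed through the life-table pipeline (life table
#' from all-cause rates, deaths partitioned by within-age cause fractions,
#' shares collapsed over age). Summing contributions over ages gives the
#' per-cause decomposition; summing over causes within level-1 groups gives
#' the age profile by broad group.
#'
#' @param rates1,rates2 age x cause rate matrices (deaths per person-year)
#'   for the two compared time points, on a common grid.
#' @param age_scheme an [age_scheme()] matching the rows.
#' @param cause_scheme a [cause_scheme()] matching the columns.
#' @param n_steps integration steps (default 20).
#' @param infant_ax passed to the life-table construction.
#' @return Object of class `f_decomposition`: list with `contribution`
#'   (age x cause matrix), `total` (`F2 - F1`), `residual`, `n_steps`,
#'   `by_cause` (cause marginals), `by_age_level1` (age x level-1 group
#'   aggregation), and the endpoint index values `F1`, `F2`.
#' @export
decompose_F_change <- function(rates1, rates2, age_scheme, cause_scheme,
                               n_steps = 20L, infant_ax = TRUE) {
  r1 <- as.matrix(rates1); r2 <- as.matrix(rates2)
  if (!all(dim(r1) == dim(r2)))
    stop("rate matrices must share the same age x cause grid")
  if (nrow(r1) != age_scheme$n_groups || ncol(r1) != cause_scheme$k)
    stop("rate matrices do not match the age/cause schemes")
  dimnames(r1) <- dimnames(r2) <- list(age_scheme$labels, cause_scheme$causes)

  f <- function(mxc) f_index_from_rates(mxc, age_scheme,
                                        infant_ax = infant_ax)
  h <- horiuchi_decompose(f, r1, r2, n_steps = n_steps)

  by_cause <- colSums(h$contribution)
  lev <- cause_scheme$level1[cause_scheme$causes]
  groups <- unique(lev)
  by_age_level1 <- sapply(groups, function(g)
    rowSums(h$contribution[, lev == g, drop = FALSE]))
  dimnames(by_age_level1) <- list(age_scheme$labels, groups)

  structure(list(contribution = h$contribution, total = h$total,
                 residual = h$residual, n_steps = h$n_steps,
                 by_cause = by_cause, by_age_level1 = by_age_level1,
                 F1 = f(r1), F2 = f(r2)),
            class = "f_decomposition")
}

#' @export
print.f_decomposition <- function(x, ...) {
  cat("<f_decomposition> Delta F = ", format(x$total, digits = 4),
      " (F1 = ", format(x$F1, digits = 4),
      ", F2 = ", format(x$F2, digits = 4), "); ",
      nrow(x$contribution), " ages x ", ncol(x$contribution), " causes\n",
      sep = "")
  top <- sort(abs(x$by_cause), decreasing = TRUE)
  cat("largest cause contributions:\n")
  for (nm in names(utils::head(top, 3L)))
    cat("  ", nm, ": ", format(x$by_cause[[nm]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Long-format export of a cause x age decomposition
#'
#' @param decomp an `f_decomposition`.
#' @param region,sex stratum labels attached to every row.
#' @return data.frame with columns `region`, `sex`, `cause`, `age_lower`,
#'   `contribution`.
#' @export
decomposition_table <- function(decomp, region = NA_character_,
                                sex = NA_character_) {
  m <- decomp$contribution
  data.frame(
    region = region, sex = sex,
    cause = rep(colnames(m), each = nrow(m)),
    age_lower = rep(vapply(rownames(m), age_label_lower, numeric(1),
                           USE.NAMES = FALSE),
                    times = ncol(m)),
    contribution = as.vector(m),
    stringsAsFactors = FALSE)
}
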