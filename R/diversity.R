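#' Fractionalization index of a cause-of-death distribution
#'
#' `F = 1 - sum(p_i^2)`: the probability that two randomly chosen deaths are
#' attributable to different causes. `F = 0` when all deaths share one cause
#' and attains its maximum `(k - 1) / k` when deaths are spread uniformly
#' over the `k` causes (20/21 ~ 0.95 for the default 21-cause scheme).
#'
#' @param p numeric vector of cause shares; must be non-negative and sum to
#'   1 within `tol`.
#' @param tol tolerance on `sum(p) = 1` (default `1e-9`).
#' @param renormalize divide by `sum(p)` instead of erroring when the sum is
#'   off by more than `tol`? Default `FALSE`.
#' @return F, dimensionless, in `[0, (k-1)/k]`.
#' @examples
#' fractionalization(rep(1 / 21, 21))   # 20/21
#' fractionalization(c(1, rep(0, 20)))  # 0
#' @export
fractionalization <- function(p, tol = 1e-9, renormalize = FALSE) {
  p <- as.numeric(p)
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0))
    stop("`p` must be finite, non-negative shares")
  s <- sum(p)
  if (abs(s - 1) > tol) {
    if (!renormalize)
      stop("cause proportions sum to ", format(s),
           ", not 1; set renormalize = TRUE to rescale")
    if (s <= 0) stop("cannot renormalize all-zero proportions")
    p <- p / s
  }
  1 - sum(p^2)
}

#' Fractionalization of observed death counts (no age-structure correction)
#'
#' The uncorrected variant: F computed directly on the observed distribution
#' of death counts across causes, without the life-table adjustment. Scale
#' invariant in the counts.
#'
#' @param death_counts non-negative per-cause death counts, not all zero.
#' @return F, dimensionless.
#' @export
fractionalization_observed <- function(death_counts) {
  x <- as.numeric(death_counts)
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop("`death_counts` must be finite and non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("`death_counts` are all zero")
  1 - sum((x / tot)^2)
}

#' Cause shares from a cause-partitioned death matrix
#'
#' Collapses a [partition_deaths_by_cause()] matrix over age:
#' `p_c = sum_x d[x, c] / sum(d)`. These are the age-structure-adjusted
#' shares that enter [fractionalization()].
#'
#' @param cdm a `cause_death_matrix` (or any non-negative age x cause
#'   matrix, not all zero).
#' @return Named numeric vector of cause shares summing to 1.
#' @export
cause_proportions_from_lifetable <- function(cdm) {
  m <- as.matrix(cdm)
  if (any(m < 0)) stop("death matrix must be non-negative")
  tot <- sum(m)
  if (tot <= 0) stop("death matrix is all zero")
  colSums(m) / tot
}

#' Regroup cause shares into a coarser scheme
#'
#' Sums shares within groups of a cause-to-group mapping (e.g. level-2
#' causes into the 3 level-1 groups). Merging causes can only decrease the
#' fractionalization index.
#'
#' @param p named numeric vector of cause shares (names are cause labels),
#'   or unnamed with `causes` supplied.
#' @param mapping named character vector: `mapping[cause] = group label`;
#'   must cover every cause.
#' @param causes cause labels for an unnamed `p`.
#' @return Named numeric vector of group shares, ordered by first appearance
#'   of each group in `mapping[causes]`.
#' @export
regroup <- function(p, mapping, causes = names(p)) {
  if (is.null(causes)) stop("`p` must be named or `causes` supplied")
  p <- stats::setNames(as.numeric(p), causes)
  miss <- setdiff(causes, names(mapping))
  if (length(miss))
    stop("mapping is missing cause(s): ", paste(miss, collapse = ", "))
  grp <- unname(mapping[causes])
  lev <- unique(grp)
  out <- vapply(lev, function(g) sum(p[grp == g]), numeric(1))
  stats::setNames(out, lev)
}

#' Male-female gap in cause-of-death diversity
#'
#' @param F_male,F_female fractionalization values.
#' @return Signed difference `F_male - F_female`.
#' @export
sex_gap <- function(F_male, F_female) {
  stopifnot(is.finite(F_male), is.finite(F_female))
  F_male - F_female
}

# F for one slice given its age x cause rate matrix: life table from the
# all-cause rates (row sums), dx partitioned by within-age cause fractions,
# collapsed over age. Hot path: bare vectors only.
f_index_from_rates <- function(mxc, age_scheme, infant_ax = TRUE) {
  summaries_from_rates(mxc, age_scheme, infant_ax = infant_ax,
                       edagger = FALSE)$F
}

# F, e0 and (optionally) e-dagger for one slice
summaries_from_rates <- function(mxc, age_scheme, infant_ax = TRUE,
                                 edagger = TRUE) {
  m <- rowSums(mxc)
  lt <- lt_core(m, age_scheme, infant_ax = infant_ax)
  pos <- m > 0
  frac <- mxc
  frac[pos, ] <- mxc[pos, , drop = FALSE] / m[pos]
  frac[!pos, ] <- 0
  p <- colSums(lt$d * frac)
  list(F = 1 - sum(p^2),
       e0 = lt$e0,
       edagger = if (edagger) edagger_core(lt) else NA_real_,
       p = p)
}
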