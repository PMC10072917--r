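# Core life-table arithmetic on bare vectors. Exported wrappers add
# validation and pretty containers; pipeline and decomposition code calls
# this directly (it is on the hot path of the Monte-Carlo and Horiuchi
# loops).
#
# Conventions: radix 1 so dx is directly the death distribution; closed
# intervals use the standard abridged conversion q = n*m / (1 + (n-a)*m)
# with a = n/2, except the infant interval [0,1) where
# a0 = 0.07 + 1.7*m0 clamped to [0.01, 0.35]; the terminal interval is open
# with q = 1 and L = l/m (constant-hazard closure).
lt_core <- function(m, scheme, infant_ax = TRUE) {
  ng <- scheme$n_groups
  if (length(m) != ng)
    stop("`m` must have one rate per age group (", ng, ")")
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop("`m` must be finite and non-negative")
  if (m[ng] <= 0)
    stop("the open terminal interval needs a positive rate to close the table")

  n <- scheme$width
  a <- n / 2
  if (infant_ax && scheme$lower[1L] == 0 && n[1L] == 1)
    a[1L] <- min(max(0.07 + 1.7 * m[1L], 0.01), 0.35)
  # open interval: exponential closure; a is the mean time to death 1/m
  a[ng] <- 1 / m[ng]

  q <- pmin(n * m / (1 + (n - a) * m), 1)
  q[ng] <- 1

  l <- c(1, cumprod(1 - q[-ng]))
  d <- l * q
  L <- n * (l - d) + a * d
  L[ng] <- l[ng] / m[ng]
  Tx <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tx / l, 0)

  list(m = m, n = n, a = a, q = q, l = l, d = d, L = L, T = Tx, e = e,
       e0 = Tx[1L])
}

# e-dagger on lt_core output: average remaining expectancy at death, with
# the within-interval death age placed at x + a and e there obtained by
# linear interpolation of T and l.
edagger_core <- function(lt) {
  ng <- length(lt$d)
  frac <- lt$a / lt$n             # position of mean death age in interval
  l_next <- c(lt$l[-1L], 0)
  l_y <- lt$l + frac * (l_next - lt$l)
  T_y <- lt$T - frac * lt$L
  ebar <- ifelse(l_y > 0, T_y / l_y, 0)
  ebar[ng] <- lt$e[ng]            # constant hazard: e flat in open interval
  sum(lt$d * ebar)
}

#' Build a period life table from all-cause mortality rates
#'
#' Constructs an abridged period life table (radix 1) from age-specific
#' all-cause mortality rates on an [age_scheme()]. Closed intervals convert
#' rates to probabilities with `q = n*m / (1 + (n - a)*m)`; the terminal
#' interval is open with `q = 1` and `L = l/m`. Average person-years lived
#' by decedents are `a = n/2`, except the infant interval where
#' `a0 = 0.07 + 1.7*m0` clamped to `[0.01, 0.35]` (a standard infant
#' separation rule; disable with `infant_ax = FALSE`).
#'
#' @param m numeric vector of all-cause rates (deaths per person-year), one
#'   per age group.
#' @param age_scheme an [age_scheme()].
#' @param infant_ax apply the infant `a0` rule when the first interval is
#'   `[0, 1)`? Default `TRUE`.
#' @return A data.frame of class `life_table` with columns `age`, `n`, `mx`,
#'   `qx`, `ax`, `lx`, `dx`, `Lx`, `Tx`, `ex` and attributes `e0` (life
#'   expectancy at birth, years) and `e_dagger` (life disparity, years).
#' @examples
#' as1 <- age_scheme(c(0:109, 110))
#' lt <- build_life_table(rep(0.05, 111), as1)
#' attr(lt, "e0")      # close to 1 / 0.05 = 20 years
#' @export
build_life_table <- function(m, age_scheme, infant_ax = TRUE) {
  core <- lt_core(m, age_scheme, infant_ax = infant_ax)
  out <- data.frame(
    age = age_scheme$lower, n = core$n, mx = core$m, qx = core$q,
    ax = core$a, lx = core$l, dx = core$d, Lx = core$L, Tx = core$T,
    ex = core$e)
  structure(out,
            class = c("life_table", "data.frame"),
            e0 = core$e0,
            e_dagger = edagger_core(core),
            age_scheme = age_scheme)
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ", nrow(x), " age groups; e0 = ",
      format(attr(x, "e0"), digits = 6), " y; e-dagger = ",
      format(attr(x, "e_dagger"), digits = 6), " y\n", sep = "")
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Life expectancy at birth of a life table
#'
#' @param lt a `life_table` from [build_life_table()].
#' @return e0 in years (`Tx[1] / lx[1]`).
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  lt$Tx[1L] / lt$lx[1L]
}

#' Life disparity (e-dagger) of a life table
#'
#' Life disparity is the average remaining life expectancy at the ages when
#' deaths occur, `sum(dx * e_at_death)`: a measure of how much lifespans
#' differ among individuals. The within-interval death age is placed at
#' `x + ax` and the remaining expectancy there is obtained by linear
#' interpolation of `Tx` and `lx`, which converges to the continuous
#' integral of `d(x) e(x)` under grid refinement.
#'
#' @param lt a `life_table` from [build_life_table()].
#' @return e-dagger in years (non-negative).
#' @export
life_disparity <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  core <- list(m = lt$mx, n = lt$n, a = lt$ax, q = lt$qx, l = lt$lx,
               d = lt$dx, L = lt$Lx, T = lt$Tx, e = lt$ex)
  edagger_core(core)
}

#' Partition life-table deaths by cause
#'
#' Splits the life-table death distribution `dx` across causes using
#' age-specific cause fractions: `d[x, c] = dx[x] * f[x, c]`. Using
#' life-table deaths (rather than observed death counts) renders populations
#' with different age structures comparable.
#'
#' @param lt a `life_table`.
#' @param cause_fractions numeric matrix, age groups x causes; every row
#'   must sum to 1 within `tol` (rows for age groups with `dx = 0` may be
#'   all zero).
#' @param tol tolerance on row sums (default `1e-9`).
#' @param renormalize divide rows by their sums instead of erroring when a
#'   row is off by more than `tol`? Default `FALSE`.
#' @return Matrix of class `cause_death_matrix` (age groups x causes) whose
#'   entries sum to 1 and whose row sums reproduce `dx`.
#' @export
partition_deaths_by_cause <- function(lt, cause_fractions, tol = 1e-9,
                                      renormalize = FALSE) {
  stopifnot(inherits(lt, "life_table"))
  f <- as.matrix(cause_fractions)
  if (nrow(f) != nrow(lt))
    stop("`cause_fractions` must have one row per age group")
  if (any(f < 0)) stop("`cause_fractions` must be non-negative")
  rs <- rowSums(f)
  need <- lt$dx > 0                  # rows that actually carry deaths
  off <- abs(rs - 1) > tol & (need | rs > 0)
  if (any(off)) {
    if (!renormalize)
      stop("cause-fraction row(s) not summing to 1 (age index ",
           paste(which(off), collapse = ", "),
           "); set renormalize = TRUE to rescale")
    pos <- rs > 0
    f[pos, ] <- f[pos, , drop = FALSE] / rs[pos]
    if (any(!pos & need))
      stop("cannot renormalize an all-zero cause-fraction row for an age ",
           "group with positive deaths (age index ",
           paste(which(!pos & need), collapse = ", "), ")")
  }
  d_xc <- lt$dx * f
  structure(d_xc, class = c("cause_death_matrix", "matrix", "array"),
            d_x = lt$dx)
}
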