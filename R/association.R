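#' Population-weighted LOESS curve
#'
#' Local polynomial regression with tricube kernel weights multiplied by
#' population weights, evaluated at a grid of predictor values. At each grid
#' point the bandwidth is the distance to the `ceiling(span * n)`-th nearest
#' observation carrying positive weight; the fitted value is the intercept
#' of a weighted least-squares polynomial of the requested degree centred at
#' the grid point. The curve is never extrapolated: the grid must lie within
#' the data range. Multiplying all weights by a positive constant leaves the
#' curve unchanged.
#'
#' @param x predictor values (e.g. life expectancy in years).
#' @param y response values (e.g. fractionalization index).
#' @param w non-negative observation weights (e.g. population sizes);
#'   default all 1.
#' @param span fraction of (positively weighted) observations in each local
#'   window, in (0, 1]; default 0.75.
#' @param degree local polynomial degree, 0, 1 or 2; default 1.
#' @param grid evaluation points; default 100 equally spaced points across
#'   the data range.
#' @return Object of class `smooth_curve`: data.frame with columns `x` and
#'   `fitted`, attributes `span` and `degree`.
#' @export
weighted_loess <- function(x, y, w = NULL, span = 0.75, degree = 1L,
                           grid = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` lengths differ")
  if (is.null(w)) w <- rep(1, n)
  w <- as.numeric(w)
  if (length(w) != n) stop("`w` must match `x` in length")
  if (anyNA(x) || anyNA(y) || anyNA(w) || any(!is.finite(c(x, y, w))))
    stop("`x`, `y`, `w` must be finite")
  if (any(w < 0)) stop("weights must be non-negative")
  if (!degree %in% 0:2) stop("`degree` must be 0, 1 or 2")
  if (span <= 0 || span > 1) stop("`span` must be in (0, 1]")

  pos <- w > 0
  npos <- sum(pos)
  if (npos < degree + 2L)
    stop("need at least degree + 2 positively weighted observations")
  if (is.null(grid))
    grid <- seq(min(x[pos]), max(x[pos]), length.out = 100L)
  grid <- as.numeric(grid)
  if (any(grid < min(x[pos]) - 1e-12) || any(grid > max(x[pos]) + 1e-12))
    stop("grid extends beyond the data range; no extrapolation")

  q <- max(ceiling(span * npos), degree + 1L)
  xp <- x[pos]; yp <- y[pos]; wp <- w[pos]
  fitted <- vapply(grid, function(x0) {
    dist <- abs(xp - x0)
    h <- sort(dist)[min(q, npos)]
    if (h <= 0) {
      if (degree >= 1)
        stop("singular local design at grid point ", format(x0),
             " (all predictor values identical in window)")
      # degree 0: the local fit degenerates to the weighted mean at x0
      at <- dist == 0
      return(sum(wp[at] * yp[at]) / sum(wp[at]))
    }
    k <- (1 - pmin(dist / h, 1)^3)^3
    wt <- k * wp
    use <- wt > 0
    if (sum(use) < degree + 1L)
      stop("window at grid point ", format(x0),
           " has too few positively weighted observations")
    X <- outer(xp[use] - x0, 0:degree, "^")
    fit <- stats::lm.wfit(X, yp[use], wt[use])
    if (any(is.na(fit$coefficients)))
      stop("singular local design at grid point ", format(x0),
           " (all predictor values identical in window)")
    fit$coefficients[1L]
  }, numeric(1))

  structure(data.frame(x = grid, fitted = fitted),
            class = c("smooth_curve", "data.frame"),
            span = span, degree = as.integer(degree))
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("<smooth_curve> ", nrow(x), " grid points on [",
      format(min(x$x), digits = 4), ", ", format(max(x$x), digits = 4),
      "]; span = ", attr(x, "span"), ", degree = ", attr(x, "degree"),
      "\n", sep = "")
  invisible(x)
}

#' Year-ordered region trajectories of diversity against longevity
#'
#' Orders per-(region, sex) series of the fractionalization index alongside
#' life expectancy and life disparity by year, for joint-trajectory plots.
#' No smoothing is applied. Years must be contiguous within each series.
#'
#' @param results data.frame with columns `region`, `sex`, `year`, `F` and
#'   any of `e0`, `edagger`.
#' @return The input rows ordered by (region, sex, year), class
#'   `region_trajectories`.
#' @export
region_trajectory <- function(results) {
  need <- c("region", "sex", "year", "F")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("`results` missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(results$region, results$sex, drop = TRUE, sep = " | ")
  gaps <- character(0)
  for (g in levels(key)) {
    yrs <- sort(results$year[key == g])
    missing_years <- setdiff(seq(min(yrs), max(yrs)), yrs)
    if (length(missing_years))
      gaps <- c(gaps, paste0("(", g, "): ",
                             paste(missing_years, collapse = ", ")))
  }
  if (length(gaps))
    stop("non-contiguous years in trajectory series:\n  ",
         paste(gaps, collapse = "\n  "))
  out <- results[order(results$region, results$sex, results$year), ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_trajectories", "data.frame")
  out
}
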