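test_that("local linear fits reproduce exact lines and constants", {
  set.seed(130)
  x <- sort(stats::runif(60, 50, 85))
  w <- stats::runif(60, 1, 100)
  for (span in c(0.3, 0.75, 1)) {
    cv <- weighted_loess(x, 2 * x + 1, w, span = span, degree = 1,
                         grid = seq(min(x) + 0.1, max(x) - 0.1,
                                    length.out = 11))
    expect_equal(cv$fitted, 2 * cv$x + 1, tolerance = 1e-9)
  }
  cv0 <- weighted_loess(x, rep(0.7, 60), w, span = 0.5, degree = 0)
  expect_equal(cv0$fitted, rep(0.7, 100), tolerance = 1e-12)
})

test_that("fitted values equal a brute-force weighted least squares oracle", {
  set.seed(131)
  n <- 80
  x <- stats::runif(n, 40, 90)
  y <- 0.9 - 0.0001 * (x - 65)^2 + stats::rnorm(n, 0, 0.02)
  w <- stats::runif(n, 1e4, 1e7)
  span <- 0.6
  for (degree in 0:2) {
    grid <- c(45, 62.5, 88)
    cv <- weighted_loess(x, y, w, span = span, degree = degree, grid = grid)
    q <- max(ceiling(span * n), degree + 1)
    for (gi in seq_along(grid)) {
      x0 <- grid[gi]
      h <- sort(abs(x - x0))[q]
      kern <- pmax(1 - pmin(abs(x - x0) / h, 1)^3, 0)^3
      wt <- kern * w
      use <- wt > 0
      X <- outer(x[use] - x0, 0:degree, "^")
      beta <- solve(t(X) %*% (wt[use] * X), t(X) %*% (wt[use] * y[use]))
      expect_equal(cv$fitted[gi], beta[1, 1], tolerance = 1e-10)
    }
  }
})

test_that("the curve is invariant to rescaling all weights", {
  set.seed(132)
  x <- stats::runif(50, 0, 10)
  y <- sin(x / 3) + stats::rnorm(50, 0, 0.05)
  w <- stats::runif(50, 1, 5)
  a <- weighted_loess(x, y, w, span = 0.7, grid = seq(1, 9, by = 1))
  b <- weighted_loess(x, y, w * 1e6, span = 0.7, grid = seq(1, 9, by = 1))
  expect_equal(a$fitted, b$fitted, tolerance = 1e-12)
})

test_that("zero-weight points are excluded from window counts", {
  # 5 informative points plus many zero-weight decoys: with span = 1 the
  # window must span only the positively weighted points
  x <- c(1:5, seq(100, 200, length.out = 30))
  y <- c(2 * (1:5), rep(-50, 30))
  w <- c(rep(1, 5), rep(0, 30))
  cv <- weighted_loess(x, y, w, span = 1, degree = 1, grid = c(2, 4))
  expect_equal(cv$fitted, c(4, 8), tolerance = 1e-9)
})

test_that("extrapolation and degenerate designs are refused", {
  x <- stats::runif(20, 0, 1)
  y <- x
  expect_error(weighted_loess(x, y, grid = c(0.5, 1.5)), "extrapolation")
  expect_error(weighted_loess(rep(1, 20), y, span = 0.5, degree = 1,
                              grid = 1),
               "singular|identical")
  expect_error(weighted_loess(x, y, w = rep(0, 20)), "positively weighted")
  expect_error(weighted_loess(x, y, span = 0), "span")
})

test_that("with span 1 on linear data the global weighted LS line returns", {
  set.seed(133)
  x <- stats::runif(40, 0, 50)
  y <- -0.004 * x + 0.9
  w <- stats::runif(40, 1, 10)
  cv <- weighted_loess(x, y, w, span = 1, degree = 1,
                       grid = seq(5, 45, by = 10))
  fit <- stats::lm(y ~ x, weights = w)
  expect_equal(cv$fitted, unname(predict(fit, data.frame(x = cv$x))),
               tolerance = 1e-9)
})

test_that("smoothing agrees with stats::loess on smooth unweighted data", {
  set.seed(134)
  x <- sort(stats::runif(120, 0, 10))
  y <- sin(x) + stats::rnorm(120, 0, 0.1)
  grid <- seq(1, 9, length.out = 15)
  ours <- weighted_loess(x, y, span = 0.75, degree = 2, grid = grid)
  ref <- stats::predict(stats::loess(y ~ x, span = 0.75, degree = 2,
                                     surface = "direct"),
                        data.frame(x = grid))
  expect_lt(max(abs(ours$fitted - ref)), 0.05)
})

test_that("region trajectories order years and detect gaps", {
  res <- expand.grid(region = c("r1", "r2"), sex = "female",
                     year = 1990:2019, stringsAsFactors = FALSE)
  res$F <- 0.8 + 0.001 * (res$year - 1990) * ifelse(res$region == "r1", 1, -1)
  res$e0 <- 60 + 0.2 * (res$year - 1990)
  shuffled <- res[sample(nrow(res)), ]
  tr <- region_trajectory(shuffled)
  expect_equal(nrow(tr), 60L)   # 2 regions x 30 years
  for (r in c("r1", "r2")) {
    path <- tr[tr$region == r, ]
    expect_equal(path$year, 1990:2019)
    expect_equal(path$F[1], res$F[res$region == r & res$year == 1990])
    expect_equal(path$F[30], res$F[res$region == r & res$year == 2019])
    # monotone F with monotone e0 traces a monotone path
    expect_true(all(diff(path$F) > 0) || all(diff(path$F) < 0))
  }
  expect_error(region_trajectory(res[res$year != 2001, ]),
               "non-contiguous.*2001")
})
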