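test_that("constant-hazard table recovers exponential closed forms", {
  as1 <- age_scheme(c(0:109, 110))
  lt <- build_life_table(rep(0.05, 111), as1)
  e0 <- attr(lt, "e0")
  ed <- attr(lt, "e_dagger")
  expect_lt(abs(e0 - 20) / 20, 0.01)           # e0 ~ 1/mu
  expect_lt(abs(ed - e0) / e0, 0.02)           # exponential: e-dagger = e0
  expect_equal(life_expectancy(lt), e0)
  expect_equal(life_disparity(lt), ed)
})

test_that("survival to the open interval collapses e0 to its start plus 1/m", {
  as_ <- gbd_age_scheme()
  m <- rep(0, 21); m[21] <- 0.5
  lt <- build_life_table(m, as_)
  expect_equal(attr(lt, "e0"), 95 + 1 / 0.5, tolerance = 1e-10)
})

test_that("immediate-death limit collapses e0 to a0", {
  as_ <- gbd_age_scheme()
  m <- rep(0.05, 21); m[1] <- 1e6
  lt <- build_life_table(m, as_)
  expect_equal(attr(lt, "e0"), lt$ax[1], tolerance = 1e-9)
  expect_equal(lt$ax[1], 0.35)  # infant a0 rule capped
})

test_that("invalid rate schedules are rejected", {
  as_ <- toy_age_scheme()
  expect_error(build_life_table(c(NA, rep(0.01, 6)), as_), "finite")
  expect_error(build_life_table(c(-0.01, rep(0.01, 6)), as_),
               "non-negative")
  expect_error(build_life_table(rep(0, 7), as_), "open terminal")
  expect_error(build_life_table(rep(0.01, 3), as_), "one rate per age")
})

test_that("random schedules satisfy the life-table invariants", {
  set.seed(100)
  for (as_ in list(toy_age_scheme(), gbd_age_scheme())) {
    for (rep_i in 1:25) {
      m <- stats::runif(as_$n_groups, 1e-5, 0.4)
      lt <- build_life_table(m, as_)
      expect_equal(sum(lt$dx), 1, tolerance = 1e-9)       # conservation
      expect_true(all(diff(lt$lx) <= 1e-12))              # lx non-increasing
      expect_equal(lt$lx[1], 1)
      expect_true(all(lt$qx >= 0 & lt$qx <= 1))
      expect_equal(lt$qx[as_$n_groups], 1)
      expect_true(all(diff(lt$Tx) <= 1e-12))              # Tx non-increasing
      expect_equal(attr(lt, "e0"), lt$Tx[1] / lt$lx[1])
      expect_gte(attr(lt, "e_dagger"), 0)
    }
  }
})

test_that("raising mortality at any single age weakly decreases e0", {
  set.seed(101)
  as_ <- toy_age_scheme()
  m <- stats::runif(as_$n_groups, 1e-4, 0.2)
  e0 <- attr(build_life_table(m, as_), "e0")
  for (j in seq_len(as_$n_groups)) {
    m2 <- m
    m2[j] <- m2[j] * 1.5
    expect_lte(attr(build_life_table(m2, as_), "e0"), e0 + 1e-12)
  }
})

test_that("life disparity matches the dense quadrature oracle", {
  # piecewise-linear lx/Tx model: per closed interval the exact integral of
  # density * T(y)/l(y) is d * [L/d + (T*d - L*l)/d^2 * log(l/(l - d))]
  oracle_edagger <- function(lt) {
    n <- nrow(lt)
    tot <- 0
    for (i in seq_len(n - 1)) {
      l0 <- lt$lx[i]; d <- lt$dx[i]; T0 <- lt$Tx[i]; L <- lt$Lx[i]
      if (d <= 0) next
      val <- if (d < 1e-14 * l0) T0 / l0 else
        L / d + (T0 * d - L * l0) / d^2 * log(l0 / (l0 - d))
      tot <- tot + d * val
    }
    tot + lt$dx[n] * lt$ex[n]
  }
  h <- 0.05
  lb <- seq(0, 120, by = h)
  mid <- lb + h / 2; mid[length(mid)] <- 122
  mu <- 3e-4 * exp(0.09 * mid)    # Gompertz adult mortality
  lt <- build_life_table(mu, age_scheme(lb), infant_ax = FALSE)
  ed <- attr(lt, "e_dagger")
  expect_lt(abs(ed - oracle_edagger(lt)) / ed, 1e-6)
})

test_that("deaths confined to a single narrow interval give e-dagger < 1 year", {
  as1 <- age_scheme(c(0:89, 90))
  m <- rep(0, 91)
  m[51] <- 1e6      # everyone dies in [50, 51)
  m[91] <- 0.5
  lt <- build_life_table(m, as1)
  expect_gt(lt$dx[51], 0.999)
  expect_lt(attr(lt, "e_dagger"), 1)
})

test_that("deaths partition by cause exactly and conserve mass", {
  set.seed(102)
  as_ <- toy_age_scheme()
  cs <- toy_cause_scheme()
  lt <- build_life_table(stats::runif(7, 0.001, 0.2), as_)

  # single cause carrying everything
  f1 <- matrix(0, 7, 3); f1[, 2] <- 1
  d1 <- partition_deaths_by_cause(lt, f1)
  expect_equal(unname(d1[, 2]), lt$dx)
  expect_equal(sum(d1), 1, tolerance = 1e-9)

  # uniform fractions
  fu <- matrix(1 / 3, 7, 3)
  du <- partition_deaths_by_cause(lt, fu)
  expect_equal(as.vector(du), as.vector(lt$dx %o% rep(1 / 3, 3)))

  # random valid fractions conserve row sums and total mass
  fr <- matrix(stats::runif(21), 7, 3)
  fr <- fr / rowSums(fr)
  dr <- partition_deaths_by_cause(lt, fr)
  expect_equal(unname(rowSums(dr)), lt$dx, tolerance = 1e-12)
  expect_equal(sum(dr), 1, tolerance = 1e-9)
})

test_that("off-sum cause fractions error unless renormalization is requested", {
  lt <- build_life_table(rep(0.05, 7), toy_age_scheme())
  bad <- matrix(1 / 3, 7, 3)
  bad[2, ] <- 0.5
  expect_error(partition_deaths_by_cause(lt, bad), "not summing to 1")
  ok <- partition_deaths_by_cause(lt, bad, renormalize = TRUE)
  expect_equal(unname(rowSums(ok)), lt$dx, tolerance = 1e-12)
  expect_error(partition_deaths_by_cause(lt, bad * -1), "non-negative")
})
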