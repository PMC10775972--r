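# Hill building blocks and the assembled drift field.

test_that("hill_activation matches its closed form and bounds", {
  expect_equal(hill_activation(0, a = 2, S = 1, n = 4), 0)
  expect_equal(hill_activation(1, a = 2, S = 1, n = 4), 1)    # half-max at S
  expect_equal(hill_activation(3.7, a = 5, S = 3.7, n = 2.5), 2.5)
  expect_equal(hill_activation(10, a = 1, S = 1, n = 4), 1e4 / (1 + 1e4))
  x <- seq(0, 5, by = 0.05)
  y <- hill_activation(x, a = 1.3, S = 0.8, n = 3)
  expect_true(all(diff(y) >= 0))          # monotone non-decreasing
  expect_true(all(y >= 0 & y <= 1.3))     # bounded in [0, a]
  expect_error(hill_activation(1, a = 1, S = 0, n = 4), "S")
  expect_error(hill_activation(-1, a = 1, S = 1, n = 4), "non-negative")
})

test_that("hill_repression matches its closed form, bounds and knockout limit", {
  expect_equal(hill_repression(0, bm = 3, b = 0.9, S = 1, n = 4), 3)
  expect_equal(hill_repression(1, bm = 1, b = 1, S = 1, n = 4), 0.5)
  expect_equal(hill_repression(100, bm = 2, b = 0.75, S = 1, n = 4),
               2 * 0.25, tolerance = 1e-6)  # floor bm (1 - b)
  # b = 0 disables repression entirely: knockout semantics
  x <- seq(0, 10, by = 0.1)
  expect_equal(hill_repression(x, bm = 1.7, b = 0, S = 1, n = 4),
               rep(1.7, length(x)))
  y <- hill_repression(x, bm = 2, b = 0.6, S = 1.5, n = 5)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 2 * 0.4 - 1e-12 & y <= 2 + 1e-12))
  expect_error(hill_repression(1, bm = 1, b = 1.2, S = 1, n = 4), "depth")
})

test_that("drift at the origin equals the zero-substrate production rates", {
  p <- base_p
  f0 <- flowering_drift(rep(0, 6), p)
  pl <- as.list(unclass(p))
  expect_equal(f0[1], hill_repression(pl$c * pl$co2, pl$bm, pl$b, pl$S, pl$n))
  expect_equal(f0[2], pl$bm21)
  expect_equal(f0[3], pl$bm34 +
                 hill_activation(pl$svp, pl$a_svp, pl$S, pl$n))
  expect_equal(f0[4], pl$bm44 + pl$bm43)
  expect_equal(f0[5], pl$bm54)
  expect_equal(f0[6], 0)
})

test_that("raising CO2 never increases miR156 production", {
  state <- c(0.5, 0.8, 0.3, 1.5, 0.4, 0.1)
  co2s <- seq(0, 1000, by = 50)
  d1 <- vapply(co2s, function(v) {
    p <- base_p; p["co2"] <- v
    flowering_drift(state, p)[1]
  }, numeric(1))
  expect_true(all(diff(d1) <= 1e-12))
  # limits: co2 = 0 gives bm; co2 -> infinity gives bm (1 - b)
  p0 <- base_p; p0["co2"] <- 0
  pl <- as.list(unclass(base_p))
  co2_term <- function(p) flowering_drift(state, p)[1] -
    hill_activation(state[2], pl$a12, pl$S, pl$n) -
    hill_activation(state[4], pl$a14, pl$S, pl$n) + pl$k * state[1]
  expect_equal(co2_term(p0), pl$bm)
  pinf <- base_p; pinf["co2"] <- 1e9
  expect_equal(co2_term(pinf), pl$bm * (1 - pl$b), tolerance = 1e-6)
})

test_that("the deterministic flow never exits the non-negative orthant", {
  # on each face x_i = 0 the drift component i is a sum of production terms
  set.seed(42)
  for (r in 1:20) {
    x <- runif(6, 0, 2)
    i <- sample(6, 1)
    x[i] <- 0
    expect_gte(flowering_drift(x, base_p)[i], 0)
  }
})

test_that("drift is bounded by production maxima and degradation", {
  ub <- production_bounds(base_p) * base_p[["k"]]
  set.seed(1)
  for (r in 1:30) {
    x <- runif(6, 0, 3)
    f <- flowering_drift(x, base_p)
    expect_true(all(f <= ub + 1e-12))
    expect_true(all(f >= -base_p[["k"]] * x - 1e-12))
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(3)
  h <- 1e-6
  for (r in 1:20) {
    x <- runif(6, 0.05, 2.5)
    J <- flowering_jacobian(x, base_p)
    Jfd <- matrix(0, 6, 6)
    for (j in 1:6) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      Jfd[, j] <- (flowering_drift(xp, base_p) -
                     flowering_drift(xm, base_p)) / (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("Jacobian has the wiring's sign structure", {
  set.seed(4)
  for (r in 1:10) {
    x <- runif(6, 0.1, 2)
    J <- flowering_jacobian(x, base_p)
    expect_lte(J[5, 4], 0)  # AP2 represses FT
    expect_gte(J[6, 5], 0)  # FT activates AP1
    expect_lte(J[2, 1], 0)  # miR156 represses SPL
    expect_gte(J[1, 2], 0)  # SPL activates miR156
  }
  # no interactions: pure decay
  J0 <- flowering_jacobian(runif(6), null_p)
  expect_equal(J0, diag(-null_p[["k"]], 6))
})
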