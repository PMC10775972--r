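# Landscape estimation: normalization, basins, saddle, Fokker-Planck
# cross-checks on reduced models.

test_that("landscape probability mass is exactly normalized", {
  set.seed(8)
  xy <- cbind(abs(rnorm(5000, 1, 0.3)), abs(rnorm(5000, 0.5, 0.2)))
  g <- landscape_from_samples(xy, bins = 40)
  expect_equal(sum(g$P), 1, tolerance = 1e-12)
  expect_true(all(is.finite(g$U[g$P > 0])))
  expect_true(all(is.infinite(g$U[g$P == 0])))
})

test_that("barrier heights are invariant to rescaling Pss", {
  toy <- make_toy_double_well(symmetric = FALSE, D = 0.3, seed = 2)
  g <- toy_landscape(toy, n_traj = 6, T = 150, seed = 2, bins = 40)
  b1 <- locate_basins_and_saddle(g, stable_points = data.frame(
    x4 = toy$minima[, 1], x6 = toy$minima[, 2]))
  g2 <- g
  g2$U <- g2$U + 3.7   # adding a constant to U = rescaling Pss
  b2 <- locate_basins_and_saddle(g2, stable_points = data.frame(
    x4 = toy$minima[, 1], x6 = toy$minima[, 2]))
  expect_equal(b2$barrier_forward, b1$barrier_forward, tolerance = 1e-12)
  expect_equal(b2$barrier_backward, b1$barrier_backward, tolerance = 1e-12)
})

test_that("the interaction-free landscape has a single minimum near the origin", {
  p <- null_p; p["D"] <- 0.02
  g <- estimate_landscape(p, n_traj = 6, T = 150, burn_in = 5, seed = 3,
                          bins = 30)
  expect_error(locate_basins_and_saddle(g), "minim")
  # the occupied region hugs the origin
  occ <- which(g$P > 0, arr.ind = TRUE)
  mids_x <- (g$x_edges[-1] + g$x_edges[-length(g$x_edges)]) / 2
  peak <- which(g$P == max(g$P), arr.ind = TRUE)[1, ]
  expect_lt(mids_x[peak[1]], 0.5)
})

test_that("baseline landscape has two basins split by a saddle, flowering deeper", {
  g <- estimate_landscape(base_p, n_traj = 10, T = 300, burn_in = 30,
                          seed = 5, bins = 60)
  bs <- locate_basins_and_saddle(g)
  expect_equal(bs$n_minima, 2)
  expect_lt(bs$flowering$U, bs$juvenile$U)          # U_a < U_b
  expect_gte(bs$saddle$U, max(bs$flowering$U, bs$juvenile$U))
  expect_lt(bs$barrier_forward, bs$barrier_backward)
  expect_gte(bs$barrier_forward, 0)
  # minima coincide with the deterministic attractors within a bin or two
  bin_w <- diff(g$x_edges[1:2])
  expect_lt(abs(bs$juvenile$x4 - base_states$juvenile[4]), 4 * bin_w)
  expect_lt(abs(bs$flowering$x4 - base_states$flowering[4]), 4 * bin_w)
})

test_that("symmetric toy landscape has symmetric barriers", {
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.3, seed = 4)
  g <- toy_landscape(toy, n_traj = 8, T = 200, seed = 4, bins = 40)
  bs <- locate_basins_and_saddle(g, stable_points = data.frame(
    x4 = toy$minima[, 1], x6 = toy$minima[, 2]))
  # equal wells: forward and backward barriers agree within sampling error
  expect_lt(abs(bs$barrier_forward - bs$barrier_backward),
            0.35 * max(bs$barrier_forward, bs$barrier_backward))
})

test_that("toy landscape U matches the Boltzmann form V/D up to a constant", {
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.2, seed = 6)
  g <- toy_landscape(toy, n_traj = 8, T = 250, seed = 6, bins = 30)
  mids_x <- (g$x_edges[-1] + g$x_edges[-length(g$x_edges)]) / 2
  mids_y <- (g$y_edges[-1] + g$y_edges[-length(g$y_edges)]) / 2
  occ <- which(is.finite(g$U) & g$P > 5e-4, arr.ind = TRUE)
  V <- toy$h * (mids_x[occ[, 1]]^2 - 1)^2 + 0.5 * mids_y[occ[, 2]]^2
  resid <- g$U[occ] - V / toy$D
  # constant offset aside, the shapes agree
  expect_gt(stats::cor(g$U[occ], V / toy$D), 0.9)
  expect_lt(stats::sd(resid), 0.8)
})

test_that("1-D Ornstein-Uhlenbeck Fokker-Planck solution is Gaussian D/k", {
  k <- 1.3; D <- 0.15
  sol <- fokker_planck_steady_state(function(z) -k * z, D = D,
                                    lower = -3, upper = 3, bins = 120)
  x <- sol$mids[[1]]
  m <- sum(sol$P * x)
  v <- sum(sol$P * (x - m)^2)
  expect_equal(m, 0, tolerance = 0.02)
  expect_equal(v, D / k, tolerance = 0.01)
  expect_equal(sum(sol$P), 1, tolerance = 1e-9)
})

test_that("2-D Fokker-Planck minima agree with the toy histogram estimate", {
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.25, seed = 9)
  sol <- fokker_planck_steady_state(toy_drift(toy), D = toy$D,
                                    lower = c(-2, -1.5), upper = c(2, 1.5),
                                    bins = c(41, 21))
  P <- sol$P
  xm <- sol$mids[[1]]
  # two probability peaks near x = -1 and x = +1, y = 0
  left <- which.max(P[xm < 0, ])
  i_left <- which(P == max(P[xm < 0, ]), arr.ind = TRUE)[1, ]
  i_right <- which(P == max(P[xm > 0, ]), arr.ind = TRUE)[1, ]
  expect_lt(abs(xm[i_left[1]] + 1), 0.15)
  expect_lt(abs(xm[i_right[1]] - 1), 0.15)
  expect_equal(sum(P), 1, tolerance = 1e-9)
})
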