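# First-passage statistics: summaries, censoring, oracles on known
# distributions and the symmetric toy.

make_samples <- function(time, censored = rep(FALSE, length(time)),
                         T_max = 1000) {
  structure(list(time = time, censored = censored,
                 n_requested = length(time), n_absorbed = sum(!censored),
                 n_censored = sum(censored), T_max = T_max, dt = 0.01,
                 start = NULL, target = NULL, r_abs = NA, seed = NA,
                 params = NULL),
            class = "fpt_samples")
}

test_that("summary of constant samples is exact", {
  s <- summarize_fpt(make_samples(rep(12.5, 40)))
  expect_equal(s$mfpt, 12.5)
  expect_equal(s$std, 0)
  expect_equal(s$censoring_fraction, 0)
})

test_that("summary recovers an exponential distribution's moments", {
  # known-distribution oracle: mean and sd of Exp(rate) are both 1/rate
  set.seed(31)
  rate <- 1 / 40
  t <- stats::rexp(4000, rate)
  s <- summarize_fpt(make_samples(t))
  se <- (1 / rate) / sqrt(4000)
  expect_lt(abs(s$mfpt - 1 / rate), 3 * se)
  expect_lt(abs(s$std - 1 / rate), 6 * se)
})

test_that("the histogram integrates to one over absorbed mass", {
  set.seed(9)
  s <- summarize_fpt(make_samples(stats::rgamma(500, 3, 0.1)), bins = 25)
  widths <- diff(s$histogram$mid)[1]
  expect_equal(sum(s$histogram$density) * widths, 1, tolerance = 0.02)
})

test_that("an all-censored ensemble yields an explicit marker, not a number", {
  s <- summarize_fpt(make_samples(rep(5, 10), censored = rep(TRUE, 10),
                                  T_max = 5))
  expect_true(s$all_censored)
  expect_true(is.na(s$mfpt))
  expect_equal(s$censoring_fraction, 1)
})

test_that("censoring accounting is conserved", {
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.08, seed = 2)
  # horizon far below the escape scale: everything censored
  f <- toy_first_passage(toy, n_traj = 12, T_max = 0.5, seed = 3)
  expect_equal(f$n_absorbed + f$n_censored, f$n_requested)
  expect_equal(f$n_censored, 12)
  expect_true(all(f$time <= f$T_max))
})

test_that("stronger noise shortens the passage over a fixed barrier", {
  toy_lo <- make_toy_double_well(symmetric = TRUE, D = 0.15, h = 0.6)
  toy_hi <- make_toy_double_well(symmetric = TRUE, D = 0.30, h = 0.6)
  lo <- summarize_fpt(toy_first_passage(toy_lo, n_traj = 80, seed = 5,
                                        T_max = 800))
  hi <- summarize_fpt(toy_first_passage(toy_hi, n_traj = 80, seed = 5,
                                        T_max = 800))
  expect_lt(hi$mfpt, lo$mfpt)
})

test_that("forward and reverse passage agree on the symmetric toy", {
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.2)
  fw <- summarize_fpt(toy_first_passage(toy, 1, 2, n_traj = 120, seed = 7,
                                        T_max = 400))
  rv <- summarize_fpt(toy_first_passage(toy, 2, 1, n_traj = 120, seed = 8,
                                        T_max = 400))
  pooled_se <- sqrt(fw$std^2 / fw$n_absorbed + rv$std^2 / rv$n_absorbed)
  expect_lt(abs(fw$mfpt - rv$mfpt), 3.5 * pooled_se)
})

test_that("toy MFPT is near the Kramers estimate (sanity anchor)", {
  # overdamped double well V = h (x^2 - 1)^2: curvature at the well 8h, at
  # the barrier 4h; Kramers MFPT = 2 pi / sqrt(8h * 4h) * exp(h / D)
  toy <- make_toy_double_well(symmetric = TRUE, D = 0.25, h = 1)
  est <- summarize_fpt(toy_first_passage(toy, n_traj = 150, seed = 9,
                                         T_max = 800))
  kramers <- 2 * pi / sqrt(32 * toy$h^2) * exp(toy$h / toy$D)
  expect_gt(est$mfpt, kramers / 3)
  expect_lt(est$mfpt, kramers * 3)
})

test_that("monostable parameter sets raise a structural error", {
  mono <- knockout(base_p, "a14")
  expect_error(first_passage_ensemble(mono, n_traj = 5), "not bistable")
})

test_that("flowering-network MFPT is reproducible and censoring-aware", {
  a <- first_passage_ensemble(base_p, n_traj = 12, T_max = 400, seed = 3)
  b <- first_passage_ensemble(base_p, n_traj = 12, T_max = 400, seed = 3)
  expect_identical(a$time, b$time)
  expect_equal(a$n_absorbed + a$n_censored, 12L)
  expect_true(all(a$time[!a$censored] < 400))
})

test_that("reverse passage is much slower than forward at baseline", {
  fw <- first_passage_ensemble(base_p, n_traj = 25, T_max = 600, seed = 13)
  rv <- reverse_passage_ensemble(base_p, n_traj = 25, T_max = 600, seed = 13)
  # the reversed process is dominated by censoring: its observed lower
  # bound exceeds the forward mean
  fw_mean <- mean(fw$time[!fw$censored])
  rv_bound <- mean(rv$time)   # censored values enter at T_max
  expect_gt(rv_bound, fw_mean)
  expect_gt(rv$n_censored, rv$n_requested * 0.5)
})
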