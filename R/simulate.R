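# Langevin dynamics: Euler-Maruyama integration of dx/dt = F(x) + eta with
# <eta(0) eta(t)> = 2 D delta(t), reflecting boundary at 0.

#' Derive a child seed from a parent seed and a counter
#'
#' Deterministic counter-based scheme used to give every ensemble member its
#' own reproducible RNG stream: a Weyl-type integer hash of `(seed, i)`
#' reduced modulo 2^31 - 1. Distinct counters give distinct seeds.
#'
#' @param seed parent integer seed.
#' @param i counter (trajectory index, >= 1).
#' @return A positive integer seed.
#' @export
child_seed <- function(seed, i) {
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  h <- (s * 48271) %% m
  h <- (h + (as.numeric(i) * 1597334677)) %% m
  as.integer(h + 1)
}

#' One Euler-Maruyama step
#'
#' Advances the state by `x + F(x) dt + sqrt(2 D dt) * z` where `z` are the
#' supplied standard-normal draws, then reflects any negative component at 0
#' so concentrations stay non-negative.
#'
#' @param state length-6 state vector.
#' @param params a [flowering_params()] object.
#' @param dt time step (days, > 0).
#' @param draws six standard-normal draws.
#' @return The next state (length-6, non-negative).
#' @export
sde_step <- function(state, params, dt, draws) {
  stopifnot(dt > 0, length(draws) == 6)
  validate_params(params)
  x <- state + flowering_drift(state, params) * dt +
    sqrt(2 * params[["D"]] * dt) * draws
  if (any(!is.finite(x))) stop("non-finite state after Euler-Maruyama step")
  abs(x)  # reflect at 0
}

#' Simulate one stochastic trajectory
#'
#' Integrates the Langevin dynamics from `x0` for `T` days at step `dt`,
#' recording every `thin`-th state. The run is bit-reproducible given
#' `(seed, dt, params)`.
#'
#' @param params a [flowering_params()] object.
#' @param x0 initial state (length-6, non-negative).
#' @param T total time (days).
#' @param dt time step (days); default 0.01.
#' @param seed integer seed.
#' @param thin record every `thin`-th step (default 1).
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix, one row per recorded time), `seed`, `dt`, `thin`, `params`.
#' @examples
#' tr <- simulate_trajectory(flowering_params(), rep(0.5, 6), T = 1, seed = 1)
#' dim(tr$states)
#' @export
simulate_trajectory <- function(params, x0, T, dt = 0.01, seed = 1, thin = 1L) {
  validate_params(params)
  stopifnot(T > dt, dt > 0, length(x0) == 6, all(x0 >= 0), thin >= 1)
  states <- withr_seed(seed, {
    sim_path_cpp(param_vector(params), as.numeric(x0), T, dt, as.integer(thin))
  })
  colnames(states) <- paste0("x", 1:6)
  structure(list(times = seq(0, by = dt * thin, length.out = nrow(states)),
                 states = states, seed = seed, dt = dt, thin = thin,
                 params = params),
            class = "trajectory")
}

#' Simulate an ensemble of independent trajectories
#'
#' Runs `n_traj` trajectories, the i-th seeded with `child_seed(seed, i)`, so
#' the ensemble is reproducible and members are statistically independent.
#'
#' @inheritParams simulate_trajectory
#' @param n_traj number of trajectories.
#' @return A list of `trajectory` objects (class `trajectory_ensemble`).
#' @export
simulate_ensemble <- function(params, x0, T, n_traj, dt = 0.01, seed = 1,
                              thin = 1L) {
  stopifnot(n_traj >= 1)
  out <- lapply(seq_len(n_traj), function(i) {
    simulate_trajectory(params, x0, T, dt = dt, seed = child_seed(seed, i),
                        thin = thin)
  })
  class(out) <- "trajectory_ensemble"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("stochastic trajectory:", nrow(x$states), "states over",
      format(max(x$times)), "days (dt =", format(x$dt),
      ", thin =", x$thin, ", seed =", x$seed, ")\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, vars = c(4, 6), ...) {
  graphics::matplot(x$times, x$states[, vars, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (days)", ylab = "expression level",
                    ...)
  graphics::legend("topright", legend = colnames(x$states)[vars],
                   col = seq_along(vars), lty = 1, bty = "n")
  invisible(x)
}
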