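# Scenario bundles: the calibrated baseline, the 2-D double-well toy with
# closed-form answers, and scaled-down variants for fast runs.

#' Baseline scenario bundle
#'
#' Packages the calibrated default parameter set at 430 ppm CO2 together with
#' its machine-checkable structural expectations (two stable states plus a
#' saddle, flowering basin deeper than juvenile, MFPT window, 810 ppm
#' advance) and a seed bank.
#'
#' @param seed integer seed for the bundle's seed bank.
#' @return An object of class `scenario_bundle`: list with `params`, `label`,
#'   `expectations` (named list), `seed`, and the run-scale fields `n_traj`,
#'   `dt`, `T_max`.
#' @export
make_baseline <- function(seed = 1) {
  structure(list(
    params = flowering_params(),
    label = "calibrated baseline, 430 ppm",
    expectations = list(
      n_stable = 2, n_saddle = 1,
      flowering_deeper = TRUE,       # U_a < U_b
      mfpt_window_days = c(70, 80),  # MFPT at 430 ppm
      co2_810_advance = 0.10,        # ~10% earlier at 810 ppm
      b21_threshold = 0.8),
    seed = seed, n_traj = 200, dt = 0.01, T_max = 1000),
    class = "scenario_bundle")
}

#' 2-D double-well toy bundle
#'
#' A two-dimensional gradient system with potential
#' `V(x, y) = h (x^2 - 1)^2 + tilt * x + y^2 / 2` whose minima (near x = -1
#' and x = +1), saddle (near x = 0) and barrier height are known in closed
#' form; its stationary distribution is the Boltzmann form
#' `Pss = exp(-V / D) / Z`, so the landscape machinery can be validated
#' against `U = V / D + const`. `symmetric = TRUE` forces equal wells
#' (tilt = 0), making forward and backward barriers and passage times equal.
#'
#' @param symmetric force equal wells.
#' @param D diffusion coefficient.
#' @param h barrier parameter of the quartic (default 1).
#' @param tilt linear asymmetry (ignored when `symmetric`).
#' @param seed integer seed.
#' @return A `scenario_bundle` with fields `h`, `tilt`, `ky`, `D`, `minima`,
#'   `saddle`, `barrier` (the potential-units barrier `V(saddle) - V(min)`),
#'   and `expectations`.
#' @export
make_toy_double_well <- function(symmetric = TRUE, D = 0.15, h = 1,
                                 tilt = 0.25, seed = 1) {
  if (symmetric) tilt <- 0
  # minima/saddle of V along x: roots of 4 h x (x^2 - 1) + tilt = 0
  rts <- sort(Re(polyroot(c(tilt, -4 * h, 0, 4 * h))))
  stopifnot(length(rts) == 3)
  vx <- function(x) h * (x^2 - 1)^2 + tilt * x
  structure(list(
    h = h, tilt = tilt, ky = 1, D = D,
    minima = rbind(c(rts[1], 0), c(rts[3], 0)),
    saddle = c(rts[2], 0),
    barrier = c(forward = vx(rts[2]) - vx(rts[1]),
                backward = vx(rts[2]) - vx(rts[3])),
    label = if (symmetric) "symmetric double well" else "tilted double well",
    expectations = list(
      symmetric_barriers = symmetric,
      boltzmann = TRUE),   # U = V / D up to a constant
    seed = seed, n_traj = 200, dt = 0.005, T_max = 400),
    class = "scenario_bundle")
}

#' Drift of a toy double-well bundle
#'
#' `-grad V` for the toy potential; usable directly with
#' [fokker_planck_steady_state()].
#'
#' @param toy a bundle from [make_toy_double_well()].
#' @return A function mapping `c(x, y)` to the 2-D drift vector.
#' @export
toy_drift <- function(toy) {
  function(z) c(-4 * toy$h * z[1] * (z[1]^2 - 1) - toy$tilt, -toy$ky * z[2])
}

#' Simulate one toy-model trajectory
#'
#' @param toy a bundle from [make_toy_double_well()].
#' @param z0 initial 2-D state.
#' @param T duration.
#' @param dt time step.
#' @param seed integer seed.
#' @param thin record every `thin`-th step.
#' @return Matrix of recorded (x, y) states.
#' @export
toy_simulate <- function(toy, z0, T, dt = toy$dt, seed = 1, thin = 1L) {
  withr_seed(seed, {
    toy_path_cpp(toy$h, toy$tilt, toy$ky, toy$D, as.numeric(z0), T, dt,
                 as.integer(thin))
  })
}

#' First-passage ensemble on the toy model
#'
#' Passage from one well to the ball of radius `r_abs` around the other,
#' using the same child-seed scheme as the flowering-network ensembles.
#'
#' @param toy a bundle from [make_toy_double_well()].
#' @param from,to well indices (1 or 2, rows of `toy$minima`).
#' @param n_traj number of trajectories.
#' @param dt time step.
#' @param T_max censoring horizon.
#' @param seed integer seed.
#' @param r_abs absorption radius (default 1/4 inter-well distance).
#' @return An `fpt_samples` object.
#' @export
toy_first_passage <- function(toy, from = 1, to = 2, n_traj = 100,
                              dt = toy$dt, T_max = toy$T_max, seed = 1,
                              r_abs = NULL) {
  z0 <- toy$minima[from, ]; zt <- toy$minima[to, ]
  if (is.null(r_abs)) r_abs <- 0.25 * sqrt(sum((z0 - zt)^2))
  time <- numeric(n_traj); cens <- logical(n_traj)
  for (i in seq_len(n_traj)) {
    r <- withr_seed(child_seed(seed, i), {
      toy_fpt_cpp(toy$h, toy$tilt, toy$ky, toy$D, z0, zt, r_abs, dt, T_max, 1L)
    })
    time[i] <- r$time[1]; cens[i] <- r$censored[1]
  }
  structure(list(time = time, censored = cens, n_requested = n_traj,
                 n_absorbed = sum(!cens), n_censored = sum(cens),
                 T_max = T_max, dt = dt, start = z0, target = zt,
                 r_abs = r_abs, seed = seed, params = NULL),
            class = "fpt_samples")
}

#' Landscape of a toy bundle from stochastic sampling
#'
#' Pools thinned trajectories started half in each well. Because the toy can
#' go negative, samples are shifted into the positive quadrant for the grid
#' and shifted back in the returned edges.
#'
#' @param toy a bundle from [make_toy_double_well()].
#' @param n_traj,T,dt,burn_in,seed,bins,thin sampling plan.
#' @return A `landscape_grid` (edges in the toy's own coordinates).
#' @export
toy_landscape <- function(toy, n_traj = 10, T = 400, dt = toy$dt,
                          burn_in = 20, seed = 1, bins = 60, thin = 10L) {
  drop_rows <- floor(burn_in / (dt * thin))
  pieces <- lapply(seq_len(n_traj), function(i) {
    z0 <- toy$minima[((i - 1) %% 2) + 1, ]
    path <- toy_simulate(toy, z0, T, dt, seed = child_seed(seed, i),
                         thin = thin)
    path[-seq_len(min(drop_rows, nrow(path) - 1)), , drop = FALSE]
  })
  xy <- do.call(rbind, pieces)
  off <- apply(xy, 2, min)
  grid <- landscape_from_samples(sweep(xy, 2, off), bins = bins)
  grid$x_edges <- grid$x_edges + off[1]
  grid$y_edges <- grid$y_edges + off[2]
  attr(grid, "toy") <- toy
  grid
}

#' Scale down a scenario bundle
#'
#' Divides the ensemble sizes by `factor` (keeping `T_max` and the physics
#' untouched) and re-derives the seed bank so child seeds do not collide
#' with the parent bundle's.
#'
#' @param bundle a `scenario_bundle`.
#' @param factor scale divisor (>= 1); refused if it would leave fewer than
#'   10 trajectories.
#' @return The scaled `scenario_bundle`.
#' @export
make_scaled_down <- function(bundle, factor = 1) {
  stopifnot(inherits(bundle, "scenario_bundle"), factor >= 1)
  n <- floor(bundle$n_traj / factor)
  if (n < 10) stop("scaling factor leaves fewer than 10 trajectories")
  bundle$n_traj <- n
  if (factor > 1) bundle$seed <- child_seed(bundle$seed, 997)
  bundle$label <- paste0(bundle$label, if (factor > 1)
    sprintf(" (scaled 1/%g)", factor) else "")
  bundle
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("scenario:", x$label, "\n")
  cat("  n_traj =", x$n_traj, ", dt =", x$dt, ", T_max =", x$T_max,
      ", seed =", x$seed, "\n")
  invisible(x)
}
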