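# shared fixtures for the test suite

# baseline calibrated parameters (430 ppm)
base_p <- flowering_params()

# a parameter set with every interaction switched off: unique stable fixed
# point at the origin, linear relaxation at rate k
null_p <- flowering_params(
  a12 = 0, a14 = 0, a32 = 0, a65 = 0, a_svp = 0,
  bm = 0, bm21 = 0, bm34 = 0, bm43 = 0, bm44 = 0, bm54 = 0)

# cached stable states of the baseline (juvenile = high X4)
base_states <- local({
  fps <- find_fixed_points(base_p, seed = 7)
  st <- fps[fps$stability == "stable", ]
  list(juvenile = as.numeric(st[which.max(st$x4), 1:6]),
       flowering = as.numeric(st[which.min(st$x4), 1:6]),
       fps = fps)
})

# deterministic relaxation by repeated D = 0 Euler steps
relax_deterministic <- function(params, x0, T = 100, dt = 0.01) {
  p <- params; p["D"] <- 0
  tr <- simulate_trajectory(p, x0, T = T, dt = dt, seed = 1,
                            thin = ceiling(T / dt))
  tr$states[nrow(tr$states), ]
}

# small test-grade FPT plan
fpt_plan_small <- list(n_traj = 60, dt = 0.01, T_max = 1500, seed = 11)
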