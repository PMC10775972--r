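# First-passage-time machinery: juvenile -> flowering transition times.

#' First-passage-time ensemble from the juvenile to the flowering state
#'
#' Starts every trajectory at the juvenile stable fixed point (the high-AP2
#' attractor) and records the first time it enters the absorption ball of
#' radius `r_abs` around the flowering fixed point, in the full 6-D state
#' space. By default `r_abs` is a quarter of the distance between the two
#' stable states, a scale-free criterion that tracks the basin geometry as
#' parameters change. Trajectories that never arrive within `T_max` days are
#' censored (recorded at `T_max`, flagged, never dropped). Trajectory `i`
#' uses `child_seed(seed, i)`, so paired-seed comparisons across scenarios
#' reuse identical noise streams per trajectory.
#'
#' @param params a bistable [flowering_params()] object.
#' @param n_traj number of trajectories (test-grade default 200).
#' @param dt Euler-Maruyama step, days.
#' @param T_max censoring horizon, days.
#' @param seed integer seed for the ensemble seed bank.
#' @param r_abs absorption radius; default 1/4 of the inter-attractor
#'   distance.
#' @param start,target optional explicit start state and target state
#'   (length-6); defaults are the juvenile and flowering fixed points.
#' @return An object of class `fpt_samples`: list with `time` (days),
#'   `censored` (logical), `n_requested`, `n_absorbed`, `n_censored`,
#'   `T_max`, `start`, `target`, `r_abs`, `seed`, `params`.
#' @export
first_passage_ensemble <- function(params, n_traj = 200, dt = 0.01,
                                   T_max = 1000, seed = 1, r_abs = NULL,
                                   start = NULL, target = NULL) {
  validate_params(params)
  stopifnot(n_traj >= 1, dt > 0, T_max > dt)
  if (is.null(start) || is.null(target)) {
    ss <- stable_states(params)  # errors if not bistable
    if (is.null(start)) start <- ss$juvenile
    if (is.null(target)) target <- ss$flowering
  }
  if (is.null(r_abs)) r_abs <- 0.25 * sqrt(sum((start - target)^2))
  pv <- param_vector(params)
  time <- numeric(n_traj); cens <- logical(n_traj)
  for (i in seq_len(n_traj)) {
    r <- withr_seed(child_seed(seed, i), {
      sim_fpt_cpp(pv, as.numeric(start), as.numeric(target), r_abs, dt,
                  T_max, 1L)
    })
    time[i] <- r$time[1]; cens[i] <- r$censored[1]
  }
  out <- structure(list(time = time, censored = cens, n_requested = n_traj,
                        n_absorbed = sum(!cens), n_censored = sum(cens),
                        T_max = T_max, dt = dt, start = start,
                        target = target, r_abs = r_abs, seed = seed,
                        params = params),
                   class = "fpt_samples")
  if (mean(cens) > 0.5)
    attr(out, "warning") <- sprintf("censoring fraction %.0f%% exceeds 50%%",
                                    100 * mean(cens))
  out
}

#' Reverse-passage ensemble (flowering back to juvenile)
#'
#' Same machinery as [first_passage_ensemble()] with start and target
#' exchanged. At the calibrated baseline the reverse barrier is much higher
#' than the forward one, so heavy censoring at any practical horizon is the
#' expected signal, not a failure.
#'
#' @inheritParams first_passage_ensemble
#' @return An `fpt_samples` object.
#' @export
reverse_passage_ensemble <- function(params, n_traj = 200, dt = 0.01,
                                     T_max = 1000, seed = 1, r_abs = NULL) {
  ss <- stable_states(params)
  first_passage_ensemble(params, n_traj = n_traj, dt = dt, T_max = T_max,
                         seed = seed, r_abs = r_abs, start = ss$flowering,
                         target = ss$juvenile)
}

#' Summarize first-passage-time samples
#'
#' Mean, standard deviation and normalized histogram of the absorbed samples;
#' the censoring fraction is carried through. With zero absorbed samples an
#' explicit all-censored summary is returned (mfpt and std are `NA`), never a
#' silent number.
#'
#' @param samples an `fpt_samples` object.
#' @param bins number of histogram bins over the absorbed range.
#' @return An object of class `fpt_summary`: list with `mfpt`, `std`,
#'   `histogram` (data.frame of bin mids and density), `censoring_fraction`,
#'   `n_absorbed`.
#' @export
summarize_fpt <- function(samples, bins = 30) {
  stopifnot(inherits(samples, "fpt_samples"))
  t_abs <- samples$time[!samples$censored]
  cf <- samples$n_censored / samples$n_requested
  if (!length(t_abs)) {
    return(structure(list(mfpt = NA_real_, std = NA_real_, histogram = NULL,
                          censoring_fraction = cf, n_absorbed = 0L,
                          all_censored = TRUE),
                     class = "fpt_summary"))
  }
  h <- graphics::hist(t_abs, breaks = bins, plot = FALSE)
  structure(list(mfpt = mean(t_abs),
                 std = if (length(t_abs) > 1) stats::sd(t_abs) else 0,
                 histogram = data.frame(mid = h$mids, density = h$density),
                 censoring_fraction = cf, n_absorbed = length(t_abs),
                 all_censored = FALSE),
            class = "fpt_summary")
}

#' @export
print.fpt_samples <- function(x, ...) {
  cat("first-passage ensemble:", x$n_requested, "trajectories,",
      x$n_absorbed, "absorbed,", x$n_censored, "censored at",
      format(x$T_max), "days\n")
  if (x$n_absorbed) {
    t_abs <- x$time[!x$censored]
    cat(sprintf("  MFPT = %.1f days, std = %.1f days\n", mean(t_abs),
                stats::sd(t_abs)))
  }
  w <- attr(x, "warning")
  if (!is.null(w)) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
print.fpt_summary <- function(x, ...) {
  if (isTRUE(x$all_censored)) {
    cat("all trajectories censored: no first-passage estimate\n")
  } else {
    cat(sprintf("MFPT = %.2f days, std = %.2f days (%d absorbed, %.0f%% censored)\n",
                x$mfpt, x$std, x$n_absorbed, 100 * x$censoring_fraction))
  }
  invisible(x)
}

#' @export
plot.fpt_summary <- function(x, ...) {
  if (isTRUE(x$all_censored)) stop("no absorbed samples to plot")
  graphics::plot(x$histogram$mid, x$histogram$density, type = "h",
                 xlab = "first passage time (days)", ylab = "density", ...)
  graphics::abline(v = x$mfpt, lty = 2)
  invisible(x)
}
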