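# Deterministic analysis: fixed points, stability, bifurcation sweeps.

#' Find the fixed points of the flowering network
#'
#' Multi-start damped-Newton root finding on the six-dimensional drift.
#' Starting points are drawn uniformly (deterministically, from `seed`) over
#' the attracting box `[0, max production / k]` in each coordinate. Converged
#' roots are deduplicated by their pairwise distance and classified by the
#' eigenvalues of the analytic Jacobian.
#'
#' @param params a [flowering_params()] object.
#' @param n_starts number of Newton starts (default 60).
#' @param seed integer seed for the start points.
#' @param tol convergence tolerance on the max-norm of the drift.
#' @param dedup_radius minimal distance between distinct fixed points.
#' @return An object of class `fixed_points`: a data.frame with columns
#'   `x1..x6`, `stability` ("stable", "saddle", "unstable" or "marginal"),
#'   `residual`, and attribute `eigen` (list of eigenvalue real parts). Empty
#'   (zero rows) with a `diagnostic` attribute if no start converged.
#' @examples
#' fps <- find_fixed_points(flowering_params())
#' fps$stability
#' @export
find_fixed_points <- function(params, n_starts = 60, seed = 1,
                              tol = 1e-10, dedup_radius = 1e-4) {
  validate_params(params)
  stopifnot(n_starts >= 1)
  bounds <- production_bounds(params)
  starts <- withr_seed(seed, {
    matrix(stats::runif(n_starts * 6), n_starts, 6) %*% diag(bounds)
  })
  roots <- list()
  for (i in seq_len(n_starts)) {
    r <- newton_root(starts[i, ], params, tol = tol)
    if (!r$ok) next
    if (!any(vapply(roots, function(z) sqrt(sum((z - r$x)^2)) < dedup_radius,
                    logical(1))))
      roots[[length(roots) + 1L]] <- r$x
  }
  if (!length(roots)) {
    out <- structure(
      data.frame(x1 = numeric(0), x2 = numeric(0), x3 = numeric(0),
                 x4 = numeric(0), x5 = numeric(0), x6 = numeric(0),
                 stability = character(0), residual = numeric(0)),
      class = c("fixed_points", "data.frame"))
    attr(out, "diagnostic") <- "no Newton start converged"
    return(out)
  }
  cls <- lapply(roots, classify, params = params)
  out <- do.call(rbind, lapply(seq_along(roots), function(i) {
    x <- roots[[i]]
    data.frame(x1 = x[1], x2 = x[2], x3 = x[3], x4 = x[4], x5 = x[5],
               x6 = x[6], stability = cls[[i]]$stability,
               residual = max(abs(flowering_drift(x, params))))
  }))
  attr(out, "eigen") <- lapply(cls, `[[`, "eigen_real")
  class(out) <- c("fixed_points", "data.frame")
  out
}

# damped Newton with projection onto the non-negative orthant
newton_root <- function(x0, params, tol = 1e-10, maxit = 200) {
  x <- pmax(as.numeric(x0), 0)
  f <- flowering_drift(x, params)
  for (i in seq_len(maxit)) {
    nf <- max(abs(f))
    if (nf < tol) return(list(x = x, ok = TRUE))
    dx <- tryCatch(solve(flowering_jacobian(x, params), -f),
                   error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, ok = FALSE))
    step <- 1
    repeat {
      xn <- pmax(x + step * dx, 0)
      fn <- flowering_drift(xn, params)
      if (max(abs(fn)) < nf || step < 1e-8) break
      step <- step / 2
    }
    if (max(abs(fn)) >= nf) return(list(x = x, ok = FALSE))
    x <- xn; f <- fn
  }
  list(x = x, ok = max(abs(f)) < tol)
}

#' Classify the stability of a fixed point
#'
#' Linearizes the drift at `state` and inspects the real parts of the
#' Jacobian eigenvalues: all negative is "stable"; exactly one positive (rest
#' negative) is "saddle"; otherwise "unstable". Eigenvalues whose real part is
#' within `tie_tol` of zero make the classification "marginal" rather than
#' silently resolving a borderline case.
#'
#' @param state a length-6 state vector with small drift residual.
#' @param params a [flowering_params()] object.
#' @param tie_tol half-width of the marginal band around zero (default 1e-8).
#' @return A list with `stability` (character) and `eigen_real` (six reals).
#' @export
classify <- function(state, params, tie_tol = 1e-8) {
  ev <- Re(eigen(flowering_jacobian(state, params), only.values = TRUE)$values)
  stability <-
    if (any(abs(ev) < tie_tol)) "marginal"
    else if (all(ev < 0)) "stable"
    else if (sum(ev > 0) == 1) "saddle"
    else "unstable"
  list(stability = stability, eigen_real = ev)
}

#' @export
print.fixed_points <- function(x, ...) {
  cat("fixed points of the flowering network (", nrow(x), " found)\n", sep = "")
  if (nrow(x)) print.data.frame(cbind(round(x[1:6], 4),
                                      stability = x$stability,
                                      residual = signif(x$residual, 2)))
  d <- attr(x, "diagnostic")
  if (!is.null(d)) cat("diagnostic:", d, "\n")
  invisible(x)
}

# the two stable states of a bistable parameter set, labeled by AP2 level:
# juvenile = high X4, flowering = low X4
stable_states <- function(params, ...) {
  fps <- find_fixed_points(params, ...)
  st <- fps[fps$stability == "stable", , drop = FALSE]
  if (nrow(st) < 2)
    stop("system is not bistable (", nrow(st), " stable fixed point(s)); ",
         "knockout scenarios need their own handling")
  juv <- st[which.max(st$x4), ]
  flw <- st[which.min(st$x4), ]
  list(juvenile = as.numeric(juv[1, 1:6]), flowering = as.numeric(flw[1, 1:6]))
}

#' Locate the loss of bistability along a one-parameter sweep
#'
#' Sweeps one parameter over a strictly monotone grid (by convention the
#' first grid value is the bistable baseline), counts stable fixed points at
#' each value, and reports the threshold: the last grid value, in sweep
#' direction, at which the system is still bistable before bistability is
#' first lost. Below this value the second basin has vanished; the grid
#' spacing is the resolution of the estimate. `NA` if bistability never
#' disappears on the grid.
#'
#' @param params baseline [flowering_params()]; must be bistable at the first
#'   grid value.
#' @param param_name name of the swept parameter, e.g. `"b21"`.
#' @param grid strictly monotone numeric vector of swept values.
#' @param ... passed to [find_fixed_points()].
#' @return An object of class `bifurcation_result`: a data.frame with one row
#'   per grid value (`value`, `n_stable`, `n_saddle`), plus attributes
#'   `threshold`, `param` and `step`.
#' @examples
#' \donttest{
#' bif <- bistability_threshold(flowering_params(), "b21", seq(1, 0.7, -0.01))
#' attr(bif, "threshold")
#' }
#' @export
bistability_threshold <- function(params, param_name, grid, ...) {
  validate_params(params)
  stopifnot(param_name %in% .param_order, length(grid) >= 2)
  dg <- diff(grid)
  if (!(all(dg > 0) || all(dg < 0))) stop("grid must be strictly monotone")
  counts <- vapply(grid, function(v) {
    p <- params; p[param_name] <- v
    fps <- find_fixed_points(p, ...)
    c(sum(fps$stability == "stable"), sum(fps$stability == "saddle"))
  }, numeric(2))
  n_stable <- counts[1, ]; n_saddle <- counts[2, ]
  if (n_stable[1] < 2)
    stop("baseline (first grid value) is not bistable for parameter '",
         param_name, "'")
  lost <- which(n_stable < 2)
  threshold <- if (length(lost)) grid[lost[1] - 1L] else NA_real_
  out <- data.frame(value = grid, n_stable = n_stable, n_saddle = n_saddle,
                    bistable = n_stable >= 2)
  attr(out, "threshold") <- threshold
  attr(out, "param") <- param_name
  attr(out, "step") <- stats::median(abs(dg))
  class(out) <- c("bifurcation_result", "data.frame")
  out
}

#' @export
print.bifurcation_result <- function(x, ...) {
  th <- attr(x, "threshold")
  cat("bifurcation sweep of", attr(x, "param"), "over", nrow(x), "values\n")
  if (is.na(th)) cat("bistability never lost on the grid\n")
  else cat("bistability lost below", format(th),
           "(grid step", format(attr(x, "step")), ")\n")
  invisible(x)
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
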