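# Hill-function building blocks and the six-equation drift field.

#' Hill activation term
#'
#' The sigmoidal activation rate `a * x^n / (S^n + x^n)`: zero at `x = 0`,
#' half-maximal at `x = S`, saturating at `a`.
#'
#' @param x regulator concentration (>= 0).
#' @param a activation strength (maximal rate, >= 0).
#' @param S Hill threshold (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Activation rate in `[0, a]`; vectorized over `x`.
#' @export
hill_activation <- function(x, a, S, n) {
  if (any(x < 0)) stop("regulator concentration must be non-negative")
  if (any(a < 0)) stop("activation strength must be non-negative")
  if (any(S <= 0)) stop("Hill threshold S must be positive")
  if (any(n < 1)) stop("Hill coefficient n must be >= 1")
  xn <- x^n
  a * xn / (S^n + xn)
}

#' Hill repression term
#'
#' The repression-form production rate `bm * (1 - b + b * S^n / (S^n + x^n))`:
#' full production `bm` at zero repressor, decreasing to the floor
#' `bm * (1 - b)` at saturating repressor. Depth `b = 1` means complete
#' shut-off; `b = 0` disables the repression entirely (knockout semantics for
#' depth-type parameters).
#'
#' @param x repressor concentration (>= 0).
#' @param bm maximal production rate (>= 0).
#' @param b repression depth in \[0, 1\].
#' @param S Hill threshold (> 0).
#' @param n Hill coefficient (>= 1).
#' @return Production rate in `[bm * (1 - b), bm]`; vectorized over `x`.
#' @export
hill_repression <- function(x, bm, b, S, n) {
  if (any(x < 0)) stop("repressor concentration must be non-negative")
  if (any(bm < 0)) stop("maximal rate bm must be non-negative")
  if (any(b < 0 | b > 1)) stop("repression depth b must lie in [0, 1]")
  if (any(S <= 0)) stop("Hill threshold S must be positive")
  if (any(n < 1)) stop("Hill coefficient n must be >= 1")
  xn <- x^n
  bm * (1 - b + b * S^n / (S^n + xn))
}

# derivative helpers for the analytic Jacobian
.dhillA <- function(x, a, S, n) a * n * S^n * x^(n - 1) / (S^n + x^n)^2
.dhillR <- function(x, bm, b, S, n) -bm * b * n * S^n * x^(n - 1) / (S^n + x^n)^2

#' Deterministic drift of the flowering network
#'
#' Evaluates the right-hand side F(x) of the six ordinary differential
#' equations. The state is (X1, ..., X6) = (miR156/157, SPL, miR172, AP2,
#' FT, AP1). CO2 enters only the miR156 equation through the composite
#' concentration `c * co2`; the fixed SVP input enters only the miR172
#' equation.
#'
#' @param state numeric length-6 state vector, all components >= 0.
#' @param params a [flowering_params()] object.
#' @return Numeric length-6 vector of rates dX/dt (day^-1 units).
#' @examples
#' flowering_drift(rep(0, 6), flowering_params())
#' @export
flowering_drift <- function(state, params) {
  stopifnot(length(state) == 6)
  if (any(state < 0)) stop("state components must be non-negative")
  validate_params(params)
  drift_cpp(as.numeric(state), param_vector(params))
}

#' Analytic Jacobian of the flowering-network drift
#'
#' The 6x6 matrix of partial derivatives of [flowering_drift()], used for
#' stability classification of fixed points and for Newton root-finding. The
#' diagonal carries `-k` plus the AP2 self-repression term in entry (4, 4).
#'
#' @inheritParams flowering_drift
#' @return A 6x6 numeric matrix.
#' @export
flowering_jacobian <- function(state, params) {
  stopifnot(length(state) == 6)
  validate_params(params)
  p <- as.list(unclass(params))
  x <- as.numeric(state)
  J <- matrix(0, 6, 6)
  diag(J) <- -p$k
  J[1, 2] <- .dhillA(x[2], p$a12, p$S, p$n)
  J[1, 4] <- .dhillA(x[4], p$a14, p$S, p$n)
  J[2, 1] <- .dhillR(x[1], p$bm21, p$b21, p$S, p$n)
  J[3, 2] <- .dhillA(x[2], p$a32, p$S, p$n)
  J[3, 4] <- .dhillR(x[4], p$bm34, p$b34, p$S, p$n)
  J[4, 3] <- .dhillR(x[3], p$bm43, p$b43, p$S, p$n)
  J[4, 4] <- J[4, 4] + .dhillR(x[4], p$bm44, p$b44, p$S, p$n)
  J[5, 4] <- .dhillR(x[4], p$bm54, p$b54, p$S, p$n)
  J[6, 5] <- .dhillA(x[5], p$a65, p$S, p$n)
  J
}

# per-species maximal production rate / k: upper bounds of the attracting box
production_bounds <- function(params) {
  p <- as.list(unclass(params))
  with(p, c(a12 + a14 + bm, bm21, a32 + bm34 + a_svp,
            bm44 + bm43, bm54, a65) / k)
}
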