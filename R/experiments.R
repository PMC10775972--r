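# The computational experiments: CO2 scans, regulation-strength scans,
# feedback knockouts, MFPT sensitivity analysis, barrier correlation.

# one FPT run -> (mfpt, std, censoring); structural marker on monostable sets
.fpt_row <- function(params, fpt_plan) {
  res <- tryCatch(
    do.call(first_passage_ensemble, c(list(params = params), fpt_plan)),
    error = function(e) e)
  if (inherits(res, "error"))
    return(list(mfpt = NA_real_, std = NA_real_, censoring = NA_real_,
                structural = conditionMessage(res), samples = NULL))
  s <- summarize_fpt(res)
  list(mfpt = s$mfpt, std = s$std, censoring = s$censoring_fraction,
       structural = NA_character_, samples = res)
}

#' Scan mean first passage time against CO2 concentration
#'
#' Runs a first-passage ensemble at each CO2 level (same seed bank across
#' levels: common random numbers) and optionally estimates the landscape to
#' attach the forward barrier height `U_c - U_b` per level.
#'
#' @param params baseline [flowering_params()].
#' @param co2_values CO2 concentrations in ppm.
#' @param fpt_plan list of arguments for [first_passage_ensemble()]
#'   (`n_traj`, `dt`, `T_max`, `seed`, ...).
#' @param barriers if `TRUE`, also compute the forward barrier per level.
#' @param landscape_plan arguments for [estimate_landscape()] when
#'   `barriers = TRUE`.
#' @return A `scan_result` data.frame: one row per CO2 value with `value`,
#'   `mfpt`, `std`, `censoring`, optional `barrier_forward`, `structural`.
#' @export
co2_scan <- function(params, co2_values = c(200, 250, 300, 400, 600, 800),
                     fpt_plan = list(), barriers = FALSE,
                     landscape_plan = list()) {
  rows <- lapply(co2_values, function(v) {
    p <- params; p["co2"] <- v
    r <- .fpt_row(p, fpt_plan)
    bf <- NA_real_
    if (barriers && is.na(r$structural)) {
      ls <- do.call(estimate_landscape, c(list(params = p), landscape_plan))
      bs <- tryCatch(locate_basins_and_saddle(ls), error = function(e) NULL)
      if (!is.null(bs)) bf <- bs$barrier_forward
    }
    data.frame(value = v, mfpt = r$mfpt, std = r$std,
               censoring = r$censoring, barrier_forward = bf,
               structural = r$structural)
  })
  out <- do.call(rbind, rows)
  attr(out, "scanned") <- "co2"
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Scan mean first passage time against one regulation parameter
#'
#' Sweeps a single parameter over `grid` at a fixed CO2 context. Depth-type
#' parameters (`b21`, `b34`, ...) are swept as absolute depths in \[0, 1\];
#' activation strengths (`a12`, `a14`, `a32`) as multiples of their baseline
#' value (`relative = TRUE`, the default for `a`-type names). Grid points
#' where the sweep destroys bistability carry a structural marker instead of
#' an MFPT. Passing a vector of CO2 values as well yields the matrix-shaped
#' two-way scan (one row per combination).
#'
#' @param params baseline [flowering_params()].
#' @param param_name swept parameter name (or `"svp"`).
#' @param grid swept values.
#' @param co2 CO2 context (scalar, or vector for a two-way scan).
#' @param fpt_plan list of arguments for [first_passage_ensemble()].
#' @param relative interpret `grid` as multiples of the baseline value;
#'   default `TRUE` for activation strengths, `FALSE` otherwise.
#' @return A `scan_result` data.frame with `value` (and `co2` for two-way
#'   scans), `mfpt`, `std`, `censoring`, `structural`.
#' @export
parameter_scan <- function(params, param_name, grid, co2 = params[["co2"]],
                           fpt_plan = list(),
                           relative = param_name %in% c("a12", "a14", "a32")) {
  stopifnot(param_name %in% .param_order)
  base_v <- params[[param_name]]
  rows <- lapply(co2, function(cv) {
    do.call(rbind, lapply(grid, function(g) {
      p <- params
      p[param_name] <- if (relative) g * base_v else g
      p["co2"] <- cv
      r <- .fpt_row(validate_params(p), fpt_plan)
      data.frame(value = g, co2 = cv, mfpt = r$mfpt, std = r$std,
                 censoring = r$censoring, structural = r$structural)
    }))
  })
  out <- do.call(rbind, rows)
  attr(out, "scanned") <- param_name
  attr(out, "relative") <- relative
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Feedback-knockout experiment
#'
#' Zeroes the named feedback parameter(s), estimates the landscape, counts
#' its basins, and (when requested and still bistable) runs the
#' first-passage analysis. Reproduces the four canonical removals: `a12`
#' (SPL -> miR156 feedback), `a14` (AP2 -> miR156), `b34` (AP2 -| miR172)
#' and `b44` (AP2 self-repression).
#'
#' @param params baseline [flowering_params()].
#' @param knockouts character vector of parameters to zero.
#' @param fpt whether to attempt the first-passage analysis.
#' @param fpt_plan arguments for [first_passage_ensemble()].
#' @param landscape_plan arguments for [estimate_landscape()].
#' @return An object of class `knockout_result`: list with `params`,
#'   `knockouts`, `n_stable`, `landscape`, `basins` (a `basin_summary` or
#'   `NULL` when a basin has vanished), `fpt` (an `fpt_samples` or `NULL`).
#' @export
knockout_experiment <- function(params, knockouts, fpt = TRUE,
                                fpt_plan = list(), landscape_plan = list()) {
  p <- knockout(params, knockouts)
  fps <- find_fixed_points(p)
  n_stable <- sum(fps$stability == "stable")
  ls <- do.call(estimate_landscape, c(list(params = p), landscape_plan))
  basins <- tryCatch(locate_basins_and_saddle(ls), error = function(e) NULL)
  fpt_res <- NULL
  if (fpt && n_stable >= 2) {
    fpt_res <- tryCatch(
      do.call(first_passage_ensemble, c(list(params = p), fpt_plan)),
      error = function(e) NULL)
  }
  structure(list(params = p, knockouts = knockouts, n_stable = n_stable,
                 landscape = ls, basins = basins, fpt = fpt_res),
            class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("knockout:", paste(x$knockouts, collapse = ", "), "->", x$n_stable,
      "stable state(s)\n")
  if (!is.null(x$basins)) print(x$basins) else
    cat("single-basin landscape (one attractor remains)\n")
  if (!is.null(x$fpt)) print(x$fpt)
  invisible(x)
}

#' Global sensitivity of the MFPT to 5% parameter decreases
#'
#' Decreases each of the nine regulation strengths (`a12`, `a14`, `b21`,
#' `a32`, `b34`, `b43`, `b44`, `b54`, `a65`) and the two inputs (`co2`,
#' `svp`) by `delta_fraction`, one at a time, and reports
#' `delta_mfpt = MFPT(perturbed) - MFPT(baseline)`. All runs reuse the same
#' seed bank (common random numbers), so small barrier shifts are not
#' drowned in Monte-Carlo noise; a paired-difference standard error is
#' reported per row. Negative values mean accelerated flowering.
#'
#' @param params baseline [flowering_params()].
#' @param delta_fraction fractional decrease (default 0.05).
#' @param fpt_plan arguments for [first_passage_ensemble()].
#' @return A `sensitivity_table` data.frame with 11 rows: `parameter`,
#'   `delta_mfpt`, `se` (paired Monte-Carlo standard error), `structural`.
#' @export
sensitivity_analysis <- function(params, delta_fraction = 0.05,
                                 fpt_plan = list()) {
  entries <- c("a12", "a14", "b21", "a32", "b34", "b43", "b44", "b54",
               "a65", "co2", "svp")
  base <- .fpt_row(params, fpt_plan)
  if (!is.na(base$structural)) stop("baseline is not bistable")
  bt <- base$samples$time; bc <- base$samples$censored
  rows <- lapply(entries, function(nm) {
    p <- params
    p[nm] <- p[[nm]] * (1 - delta_fraction)
    r <- .fpt_row(validate_params(p), fpt_plan)
    if (!is.na(r$structural))
      return(data.frame(parameter = nm, delta_mfpt = NA_real_, se = NA_real_,
                        structural = r$structural))
    keep <- !bc & !r$samples$censored
    d <- r$samples$time[keep] - bt[keep]
    data.frame(parameter = nm, delta_mfpt = mean(d),
               se = stats::sd(d) / sqrt(length(d)),
               structural = NA_character_)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_mfpt") <- base$mfpt
  attr(out, "delta_fraction") <- delta_fraction
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Correlation between log MFPT and forward barrier height
#'
#' Pairs `ln(MFPT)` with `barrier_forward` across the rows of a scan and
#' reports the Pearson correlation, the discrete analogue of the
#' Arrhenius-like relation between transition time and barrier height.
#'
#' @param scan a `scan_result` with a `barrier_forward` column (e.g. from
#'   [co2_scan()] with `barriers = TRUE`).
#' @return List with `r` (Pearson correlation, `NA` with marker if the
#'   barrier is degenerate), `pairs` (data.frame of barrier and log-MFPT).
#' @export
barrier_correlation <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  ok <- is.finite(scan$mfpt) & is.finite(scan$barrier_forward)
  if (sum(ok) < 3)
    stop("need at least 3 rows with both MFPT and barrier height")
  pairs <- data.frame(barrier = scan$barrier_forward[ok],
                      log_mfpt = log(scan$mfpt[ok]))
  if (stats::sd(pairs$barrier) == 0 || stats::sd(pairs$log_mfpt) == 0)
    return(list(r = NA_real_, degenerate = TRUE, pairs = pairs))
  list(r = stats::cor(pairs$barrier, pairs$log_mfpt), degenerate = FALSE,
       pairs = pairs)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan of", attr(x, "scanned"), "over", nrow(x), "points\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("MFPT sensitivity to a %.0f%% parameter decrease (baseline %.1f days)\n",
              100 * attr(x, "delta_fraction"), attr(x, "baseline_mfpt")))
  cat("negative values mean accelerated flowering\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
plot.scan_result <- function(x, what = "mfpt", ...) {
  graphics::plot(x$value, x[[what]], type = "b", xlab = attr(x, "scanned"),
                 ylab = what, ...)
  invisible(x)
}

#' @export
plot.sensitivity_table <- function(x, ...) {
  graphics::barplot(x$delta_mfpt, names.arg = x$parameter, las = 2,
                    ylab = "change in MFPT (days)", ...)
  graphics::abline(h = 0)
  invisible(x)
}
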