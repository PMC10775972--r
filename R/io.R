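# Plain-text persistence for analysis results: tidy CSV for tabular
# objects, JSON for summaries.

#' Write an analysis result to CSV
#'
#' Tabular results write one row per grid value or scan point:
#' `bifurcation_result` and `scan_result` as-is, a `landscape_grid` as
#' (bin center x4, bin center x6, Pss, U) over occupied bins, and a
#' `sensitivity_table` as its 11 rows.
#'
#' @param x a `bifurcation_result`, `scan_result`, `sensitivity_table` or
#'   `landscape_grid`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  df <- if (inherits(x, "landscape_grid")) {
    occ <- which(is.finite(x$U), arr.ind = TRUE)
    xm <- .bin_mids(x$x_edges); ym <- .bin_mids(x$y_edges)
    data.frame(x4 = xm[occ[, 1]], x6 = ym[occ[, 2]],
               Pss = x$P[occ], U = x$U[occ])
  } else if (inherits(x, "fpt_samples")) {
    data.frame(time = x$time, censored = x$censored)
  } else if (is.data.frame(x)) {
    as.data.frame(x)
  } else stop("no CSV representation for class ", class(x)[1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis summary to JSON
#'
#' `basin_summary` and `fpt_summary` objects (and the metadata of an
#' `fpt_samples` ensemble) serialize to a flat JSON object.
#'
#' @param x a `basin_summary`, `fpt_summary` or `fpt_samples`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  obj <- if (inherits(x, "basin_summary")) {
    unclass(x)
  } else if (inherits(x, "fpt_summary")) {
    x["histogram"] <- NULL
    unclass(x)
  } else if (inherits(x, "fpt_samples")) {
    list(n_requested = x$n_requested, n_absorbed = x$n_absorbed,
         n_censored = x$n_censored, T_max = x$T_max, dt = x$dt,
         r_abs = x$r_abs, seed = x$seed, start = x$start,
         target = x$target)
  } else stop("no JSON representation for class ", class(x)[1])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
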