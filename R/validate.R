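#' Recoil sensitivity study
#'
#' Runs the recoil phase (ablation to t = 6 min, no purse-string
#' contractility) on a calibration patch for a grid of values of one
#' material parameter and reports the apical wound area at the end of
#' recoil. Used to check the calibration trends: recoil increases with the
#' intrinsic contractility and with the remodeling rate, and decreases with
#' the elastic vertex stiffness.
#'
#' @param centers cell-center table (typically a 65-cell calibration patch).
#' @param ablated_cell_ids cells to ablate.
#' @param parameter one of `"eps_c"`, `"gamma"`, `"k_V0"`.
#' @param grid numeric vector of parameter values.
#' @param params base [material_params()].
#' @param settings [solver_settings()].
#' @param t_recoil end of the recoil phase (min).
#' @param ... passed to [run_simulation()].
#' @return tibble with columns `parameter`, `value`, `recoil_area_um2`,
#'   `converged`.
#' @export
recoil_sensitivity_study <- function(centers, ablated_cell_ids,
                                     parameter = c("eps_c", "gamma", "k_V0"),
                                     grid, params = material_params(),
                                     settings = solver_settings(), t_recoil = 6,
                                     ...) {
  parameter <- match.arg(parameter)
  rows <- lapply(grid, function(v) {
    p <- params
    p[[parameter]] <- v
    prot <- wound_protocol(ablated_cell_ids, Y_Ac = 0, Y_Lc = 0)
    sim <- tryCatch(
      run_simulation(centers, p, prot, settings, t_end = t_recoil, ...),
      error = function(e) NULL)
    ok <- !is.null(sim) && !isTRUE(sim$summary$aborted)
    tibble::tibble(parameter = parameter, value = v,
                   recoil_area_um2 = if (ok)
                     sim$timeseries$wound_area_um2[nrow(sim$timeseries)] else NA_real_,
                   converged = ok)
  })
  dplyr::bind_rows(rows)
}

#' Closure-threshold search by bisection
#'
#' Locates the critical apical purse-string amplitude below which the wound
#' fails to close, at a given resolution, by bisection on the closed/open
#' outcome. The endpoints must straddle the transition; if the upper
#' endpoint fails to close the search can optionally widen the bracket.
#'
#' @param centers cell-center table.
#' @param ablated_cell_ids cells to ablate.
#' @param bracket numeric length-2: lower (non-closing) and upper (closing)
#'   amplitudes.
#' @param resolution grid resolution of the returned amplitude.
#' @param params,settings model and solver settings.
#' @param t_end simulated time horizon per run (min).
#' @param Y_Lc lateral amplitude held fixed.
#' @param widen if `TRUE`, double the upper endpoint (up to `max_Y`) when it
#'   does not close instead of erroring.
#' @param max_Y cap for bracket widening.
#' @param runner optional memoised function `function(Y) logical(closed)`;
#'   by default runs [run_simulation()] per amplitude.
#' @param ... passed to [run_simulation()].
#' @return list with `threshold` (smallest closing amplitude on the grid),
#'   `runs` (tibble of amplitude, closed).
#' @export
closure_threshold_search <- function(centers, ablated_cell_ids,
                                     bracket = c(1.5, 3.0), resolution = 0.1,
                                     params = material_params(),
                                     settings = solver_settings(),
                                     t_end = 150, Y_Lc = 0,
                                     widen = FALSE, max_Y = 12,
                                     runner = NULL, ...) {
  cache <- new.env(parent = emptyenv())
  if (is.null(runner)) {
    dots <- list(...)
    runner <- function(Y) {
      prot <- wound_protocol(ablated_cell_ids, Y_Ac = Y, Y_Lc = Y_Lc)
      sim <- tryCatch(
        do.call(run_simulation,
                c(list(centers, params, prot, settings, t_end = t_end), dots)),
        error = function(e) NULL)
      !is.null(sim) && isTRUE(sim$summary$closed)
    }
  }
  closed_at <- function(Y) {
    key <- sprintf("%.6f", Y)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- runner(Y)
    cache[[key]]
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  if (closed_at(lo)) stop("lower bracket endpoint already closes; lower it")
  while (!closed_at(hi)) {
    if (!widen || hi >= max_Y) {
      stop("upper bracket endpoint does not close; widen the bracket")
    }
    lo <- hi
    hi <- min(max_Y, hi * 2)
  }
  while (hi - lo > resolution + 1e-9) {
    mid <- round((lo + hi) / 2 / resolution) * resolution
    if (mid <= lo || mid >= hi) break
    if (closed_at(mid)) hi <- mid else lo <- mid
  }
  runs <- tibble::tibble(
    Y_Ac = as.numeric(ls(cache)),
    closed = vapply(ls(cache), function(k) cache[[k]], logical(1L)))
  runs <- runs[order(runs$Y_Ac), ]
  list(threshold = hi, runs = runs)
}
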