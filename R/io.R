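#' Default run configuration
#'
#' All tunable parameters of a simulation with their calibrated defaults,
#' grouped as `patch`, `material`, `solver` and `wound` blocks. The material
#' block carries the recoil-phase calibration (eps_c = 1.3, k_V0 = 0.05,
#' gamma = 0.2, k_N = 0.3, k_V = 1.0, lambda_Vol = 20), the solver block the
#' theta = 0.5 scheme with dt = 0.6/1.0 min and tolerance 1e-10, the wound
#' block the purse-string schedule (t_w = 6 min, 400 min decay span).
#'
#' @return nested list of class `epi_config`.
#' @export
default_config <- function() {
  structure(list(
    patch = list(n_cells = 80L, spacing = 12, noise_amplitude = 0.15,
                 height = 35, seed = 1L),
    material = list(k_N = 0.3, k_V = 1.0, k_V0 = 0.05, lambda_Vol = 20,
                    eps_c = 1.3, gamma = 0.2),
    solver = list(theta = 0.5, dt_recoil = 0.6, dt_closure = 1.0,
                  t_recoil = 6, newton_tol = 1e-10, max_newton_iters = 80L,
                  max_halvings = 12L, tol_r = 0.1),
    wound = list(n_ablate = 5L, Y_Ac = 2.3, Y_Lc = 0, t_w = 6,
                 decay_span = 400, stiffness_factor = 0.01,
                 removal_area_fraction = 0.8, closure_area_fraction = 0.02),
    run = list(t_end = 150, prestrain = TRUE)
  ), class = "epi_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills missing entries with [default_config()] values,
#' and rejects unknown keys with an itemized error. An empty file yields the
#' pure defaults.
#'
#' @param path YAML file path.
#' @return validated `epi_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  base <- default_config()
  problems <- character(0)
  for (block in names(user)) {
    if (!block %in% names(base)) {
      problems <- c(problems, paste0("unknown block '", block, "'"))
      next
    }
    for (key in names(user[[block]])) {
      if (!key %in% names(base[[block]])) {
        problems <- c(problems, paste0("unknown key '", block, ".", key, "'"))
      } else {
        base[[block]][[key]] <- user[[block]][[key]]
      }
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  validate_config(base)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg)
  m <- cfg$material
  for (f in names(m)) chk(is.numeric(m[[f]]) && m[[f]] >= 0,
                          paste0("material.", f, " must be non-negative"))
  chk(cfg$patch$n_cells >= 7, "patch.n_cells must be >= 7")
  chk(cfg$patch$noise_amplitude >= 0 && cfg$patch$noise_amplitude < 0.5,
      "patch.noise_amplitude must be in [0, 0.5)")
  chk(cfg$solver$theta >= 0 && cfg$solver$theta <= 1,
      "solver.theta must be in [0, 1]")
  chk(cfg$solver$tol_r >= 0, "solver.tol_r must be non-negative")
  chk(cfg$wound$stiffness_factor > 0 && cfg$wound$stiffness_factor < 1,
      "wound.stiffness_factor must be in (0, 1)")
  chk(cfg$wound$Y_Ac >= 0, "wound.Y_Ac must be non-negative")
  chk(cfg$wound$Y_Lc >= 0, "wound.Y_Lc must be non-negative")
  cfg
}

#' Write a configuration to YAML
#' @param cfg an `epi_config`.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# construct the model objects described by a config
config_objects <- function(cfg) {
  list(
    spec = patch_spec(cfg$patch$n_cells, spacing = cfg$patch$spacing,
                      noise_amplitude = cfg$patch$noise_amplitude,
                      height = cfg$patch$height, seed = cfg$patch$seed),
    params = do.call(material_params, cfg$material),
    settings = do.call(solver_settings, cfg$solver))
}

#' Run a simulation from a configuration
#'
#' Generates the seeded patch, selects the central ablation region, runs the
#' wound protocol, and (optionally) writes a self-describing run directory:
#' resolved config, centers CSV, per-step timeseries CSV, summary JSON and
#' VTK frames.
#'
#' @param cfg an `epi_config` (see [default_config()], [load_config()]).
#' @param out_dir optional output directory.
#' @param frames write VTK frames (only with `out_dir`).
#' @param verbose print per-step diagnostics.
#' @return an `epi_sim`.
#' @export
run_config <- function(cfg, out_dir = NULL, frames = FALSE, verbose = FALSE) {
  ob <- config_objects(cfg)
  centers <- generate_hex_patch(ob$spec)
  abl <- select_ablation_region(centers, cfg$wound$n_ablate)
  protocol <- wound_protocol(abl, Y_Ac = cfg$wound$Y_Ac, Y_Lc = cfg$wound$Y_Lc,
                             t_w = cfg$wound$t_w,
                             decay_span = cfg$wound$decay_span,
                             stiffness_factor = cfg$wound$stiffness_factor,
                             removal_area_fraction = cfg$wound$removal_area_fraction,
                             closure_area_fraction = cfg$wound$closure_area_fraction)
  frame_dir <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_config(cfg, file.path(out_dir, "config.yaml"))
    write_centers(centers, file.path(out_dir, "centers.csv"))
    if (frames) frame_dir <- file.path(out_dir, "frames")
  }
  sim <- run_simulation(centers, ob$params, protocol, ob$settings,
                        t_end = cfg$run$t_end, height = cfg$patch$height,
                        prestrain = cfg$run$prestrain,
                        frame_dir = frame_dir, verbose = verbose)
  if (!is.null(out_dir)) {
    readr::write_csv(sim$timeseries, file.path(out_dir, "timeseries.csv"))
    jsonlite::write_json(as.list(sim$summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  sim
}

#' Export the current monolayer state as a legacy-VTK frame
#'
#' Writes an ASCII POLYDATA file with the apical and basal cell polygons and
#' the lateral vertex segments as lines, plus per-polygon cell id and
#' relative volume change fields. Coordinates are in micrometers.
#'
#' @param ml a `monolayer`.
#' @param path output file (.vtk).
#' @export
write_vtk_frame <- function(ml, path) {
  Xp <- ml_points(ml) * ml$scale
  cells <- ml$topo$cells
  vols <- cell_volumes(ml)
  polys <- list(); ids <- integer(0); dvol <- numeric(0)
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    V0 <- ml$nodes$V0[cl$node]
    dv <- if (is.na(V0) || V0 <= 0) 0 else (vols[[k]] - V0) / V0
    polys <- c(polys, list(cl$loop_a - 1L), list(cl$loop_b - 1L))
    ids <- c(ids, cl$node, cl$node)
    dvol <- c(dvol, dv, dv)
  }
  lat <- ml$topo$segments[ml$topo$segments$orientation %in%
                            c("lateral_vertical", "lateral_diagonal") &
                            ml$topo$segments$network == "vertex", ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("epithelial monolayer t=", format(ml$time), " min"),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(Xp), "double")), con)
  utils::write.table(format(Xp, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  sizes <- lengths(polys)
  writeLines(paste("POLYGONS", length(polys), sum(sizes + 1L)), con)
  writeLines(vapply(polys, function(p) paste(c(length(p), p), collapse = " "),
                    character(1L)), con)
  writeLines(paste("LINES", nrow(lat), 3L * nrow(lat)), con)
  writeLines(paste(2L, lat$p1 - 1L, lat$p2 - 1L), con)
  writeLines(c(paste("CELL_DATA", length(polys) + nrow(lat)),
               "SCALARS cell_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(ids, rep(-1L, nrow(lat)))), con)
  writeLines(c("SCALARS rel_volume_change double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(c(dvol, rep(0, nrow(lat))), digits = 8), con)
  invisible(path)
}

#' Sweep one wound parameter over a grid
#'
#' Repeats [run_config()] over a grid of values of a single wound-protocol or
#' material parameter and collects one summary row per value.
#'
#' @param cfg base `epi_config`.
#' @param parameter name, e.g. `"Y_Ac"`, `"Y_Lc"` (wound block) or
#'   `"lambda_Vol"`, `"gamma"`, `"eps_c"`, `"k_V0"` (material block).
#' @param values numeric grid.
#' @return tibble with one row per value (value plus [glance.epi_sim()]
#'   columns).
#' @export
sweep_parameter <- function(cfg, parameter, values) {
  rows <- lapply(values, function(v) {
    c2 <- cfg
    if (parameter %in% names(c2$wound)) c2$wound[[parameter]] <- v
    else if (parameter %in% names(c2$material)) c2$material[[parameter]] <- v
    else stop("unknown sweep parameter: ", parameter)
    sim <- tryCatch(run_config(c2), error = function(e) NULL)
    out <- if (is.null(sim)) {
      tibble::tibble(closed = NA, closure_time_min = NA_real_,
                     recoil_area_um2 = NA_real_, final_area_um2 = NA_real_,
                     final_rel_height = NA_real_, max_mean_vol_dev = NA_real_,
                     n_steps = NA_integer_, aborted = TRUE, t_abort_min = NA_real_)
    } else {
      glance(sim)
    }
    dplyr::bind_cols(tibble::tibble(value = v), out)
  })
  dplyr::bind_rows(rows)
}
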