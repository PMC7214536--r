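#' Newton-Raphson solve of mechanical equilibrium over one time step
#'
#' Minimizes the total energy with respect to the free degrees of freedom
#' (cell-center nodes plus relaxed and intermediate vertices), with the
#' theta-weighted rest-length update substituted implicitly so each Newton
#' iterate sees rest lengths consistent with its trial geometry. The search
#' direction is the Newton step when the tangent is positive definite and a
#' tau-shifted (modified Cholesky) direction otherwise, followed by a
#' backtracking Armijo line search on the energy, so W decreases
#' monotonically across iterates even on the nonconvex parts of the
#' landscape. Convergence
#' requires both ||dx|| and ||g|| below `settings$newton_tol`. On exit the
#' viscoelastic rest lengths are updated consistently with the final
#' positions and constrained vertices remain exactly interpolated.
#'
#' @param ml a `monolayer`.
#' @param params [material_params()].
#' @param t time at the end of the step (min), used for the contractility
#'   schedule when a wound protocol is active.
#' @param dt time step (min); `NULL` or 0 solves a static equilibrium with
#'   frozen rest lengths.
#' @param settings [solver_settings()].
#' @param protocol optional [wound_protocol()] supplying contractility.
#' @return list with the converged `monolayer` (`ml`), `iters`, `converged`,
#'   and final residual norm `gnorm`.
#' @export
newton_solve <- function(ml, params, t = 0, dt = NULL,
                         settings = solver_settings(), protocol = NULL) {
  contract <- if (is.null(protocol)) c(0, 0) else contractility_schedule(t, protocol)
  rest <- if (is.null(dt) || !is.numeric(dt) || dt <= 0) "frozen" else "implicit"
  dt_use <- if (rest == "implicit") dt else NULL
  if (is.null(ml$cache)) ml$cache <- build_assembly_cache(ml)
  l_ref <- segment_lengths(ml)
  args <- list(ml = ml, params = params, contract = contract, rest = rest,
               dt = dt_use, theta = settings$theta, l_ref = l_ref)

  Xd <- ml_dof_positions(ml)
  free <- ml$cache$free_coords
  r <- do.call(residual, c(args, list(Xd = Xd)))
  E <- do.call(energy_total, c(args, list(Xd = Xd)))
  gnorm <- r$norm
  iters <- 0L
  converged <- gnorm < settings$newton_tol
  while (!converged && iters < settings$max_newton_iters) {
    H <- do.call(jacobian, c(args, list(Xd = Xd)))
    # descent direction: Newton when the tangent is positive definite, else
    # a tau-shifted (modified) factorization so W decreases monotonically
    delta <- NULL
    tau <- 0
    dscale <- max(abs(Matrix::diag(H)), 1)
    repeat {
      Hs <- if (tau > 0) H + Matrix::Diagonal(length(r$g), tau) else H
      ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Hs), perm = TRUE),
                     error = function(e) NULL)
      if (!is.null(ch)) {
        delta <- -as.numeric(Matrix::solve(ch, r$g))
        if (sum(delta * r$g) < 0) break
      }
      tau <- if (tau == 0) 1e-6 * dscale else 10 * tau
      if (tau > 1e12 * dscale) stop("tangent modification failed")
    }
    # trust cap: an ill-conditioned tangent can produce an arbitrarily long
    # step; limit its norm so backtracking starts from a sane trial
    dn <- sqrt(sum(delta^2))
    if (dn > 0.5) delta <- delta * (0.5 / dn)
    alpha <- 1
    slope <- sum(r$g * delta)
    ls_ok <- FALSE
    repeat {
      Xtry <- apply_step(Xd, delta, free, alpha)
      Etry <- do.call(energy_total, c(args, list(Xd = Xtry)))
      # the absolute slack keeps the test meaningful when the predicted
      # decrease falls below the roundoff level of E (final Newton steps)
      if (is.finite(Etry) &&
          Etry <= E + 1e-4 * alpha * slope + 1e-12 * (abs(E) + 1e-12)) {
        ls_ok <- TRUE
        break
      }
      alpha <- alpha / 2
      if (alpha < 2^-16) break
    }
    if (!ls_ok) break  # no descent possible (energy kink, e.g. a junction
                       # crushed to zero length awaiting a topological move)
    Xd <- Xtry
    E <- Etry
    r <- do.call(residual, c(args, list(Xd = Xd)))
    gnorm <- r$norm
    iters <- iters + 1L
    dx <- sqrt(sum((alpha * delta)^2))
    converged <- gnorm < settings$newton_tol && dx < settings$newton_tol
    if (!is.finite(gnorm)) break
  }
  ml <- ml_set_dof_positions(ml, Xd)
  if (rest == "implicit" && converged) {
    co <- theta_coeffs(ml$topo$segments$L, l_ref, dt, settings$theta,
                       params$gamma, segment_eps_c(ml, params))
    l_new <- segment_lengths(ml)
    gm <- ml$topo$segments$gamma_on
    Lnew <- ifelse(gm, co$A + co$B * l_new, ml$topo$segments$L)
    if (any(Lnew <= 0)) stop("rest length became non-positive during update")
    ml$topo$segments$L <- Lnew
    ml$seg_state$L <- Lnew
  }
  list(ml = ml, iters = iters, converged = converged, gnorm = gnorm)
}

apply_step <- function(Xd, delta, free_coords, alpha) {
  x <- as.numeric(t(Xd))
  x[free_coords] <- x[free_coords] + alpha * delta
  matrix(x, ncol = 3L, byrow = TRUE)
}

#' Run a wound-healing simulation
#'
#' Advances the monolayer through the standard protocol: a settle solve, an
#' optional homeostatic prestrain, ablation at t = 0, then time stepping with
#' dt = `settings$dt_recoil` during recoil (t <= `settings$t_recoil`) and
#' `settings$dt_closure` afterwards. Each step applies the contractility
#' schedules, solves equilibrium, remeshes both layers under the aspect-ratio
#' rule, maintains the wound (removal of degraded cells, closure detection)
#' and records observables. Failed steps are retried with halved dt up to
#' `settings$max_halvings` times; the schedule step is restored afterwards.
#' Deterministic for fixed inputs.
#'
#' @param centers cell-center table (`cell_id`, `x_um`, `y_um`).
#' @param params [material_params()].
#' @param protocol [wound_protocol()] (or `NULL` for an unwounded run).
#' @param settings [solver_settings()].
#' @param t_end end time (min).
#' @param height monolayer height (um).
#' @param length_scale normalization length for the mechanics (um); the
#'   calibrated parameters presume height-normalized lengths, hence the
#'   default `height`.
#' @param prestrain apply the homeostatic viscoelastic prestrain
#'   L = l/(1+eps_c) to the junctional (in-plane vertex) segments before
#'   ablation: the tissue's contractile steady state, whose pre-existing
#'   tension drives the recoil.
#' @param frame_dir optional directory for per-step VTK frames.
#' @param stop_at_closure stop stepping once the wound has closed.
#' @param verbose print per-step diagnostics.
#' @return object of class `epi_sim`: list with `timeseries` (tibble),
#'   `monolayer`, `summary` (closure time, closed flag, recoil area, final
#'   relative height), `params`, `protocol`, `settings`.
#' @export
run_simulation <- function(centers, params = material_params(),
                           protocol = NULL, settings = solver_settings(),
                           t_end = 150, height = 35, length_scale = height,
                           prestrain = TRUE,
                           frame_dir = NULL, stop_at_closure = TRUE,
                           verbose = FALSE) {
  ml <- build_monolayer(centers, height = height, length_scale = length_scale)
  if (prestrain) ml <- prestrain_monolayer(ml, params)
  # settle to the pre-ablation equilibrium
  st <- newton_solve(ml, params, t = 0, dt = NULL, settings = settings)
  if (!st$converged) stop("settle solve did not converge (||g|| = ", st$gnorm, ")")
  ml <- st$ml
  if (!is.null(protocol)) ml <- ablate(ml, protocol)

  rows <- list()
  frame <- 0L
  record <- function(ml, t, iters, dt) {
    vd <- volume_deviation_stats(ml)
    wc <- wound_edge_counts(ml)
    tibble::tibble(t_min = t,
                   wound_area_um2 = apical_wound_area(ml),
                   rel_height = relative_height(ml, height),
                   n_edge_cells = wc[[1L]],
                   mean_vol_dev = vd[[1L]], max_vol_dev = vd[[2L]],
                   newton_iters = iters, dt_min = dt)
  }
  rows[[1L]] <- record(ml, 0, st$iters, NA_real_)
  if (!is.null(frame_dir)) {
    dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk_frame(ml, file.path(frame_dir, sprintf("frame_%04d.vtk", frame)))
  }

  t <- 0
  while (t < t_end - 1e-9) {
    dt_sched <- if (t < settings$t_recoil - 1e-9) settings$dt_recoil else settings$dt_closure
    dt_sched <- min(dt_sched, t_end - t)
    dt <- dt_sched
    attempts <- 0L
    ml_try <- ml
    last_g <- Inf
    ok <- FALSE
    while (!ok) {
      res <- tryCatch(
        newton_solve(ml_try, params, t = t + dt, dt = dt, settings = settings,
                     protocol = protocol),
        error = function(e) e)
      if (!inherits(res, "error") && res$converged) {
        ok <- TRUE
        break
      }
      attempts <- attempts + 1L
      if (attempts > settings$max_halvings) {
        msg <- if (inherits(res, "error")) conditionMessage(res) else
          paste0("Newton stalled at ||g|| = ", format(res$gnorm))
        warning("run aborted at t = ", t, " min after ", settings$max_halvings,
                " attempts: ", msg, call. = FALSE)
        return(finish_sim(rows, ml, params, protocol, settings,
                          aborted = TRUE, t_abort = t))
      }
      if (inherits(res, "error")) {
        dt <- dt / 2
        next
      }
      # continue from the partially descended state (energy descent is
      # monotone, so progress is never lost); a stalled solve usually means
      # the minimum requires a topological move, so remesh first, then if
      # stagnating force-remove the most crushed degraded cell, then halve
      base <- res$ml
      changed <- FALSE
      mlr <- tryCatch({
        m2 <- remesh_step(base, settings$tol_r)
        if (!is.null(protocol)) m2 <- maintain_wound(m2, protocol) else m2
      }, error = function(e) NULL)
      if (!is.null(mlr)) {
        changed <- !identical(mlr$seg_state$key, base$seg_state$key)
        base <- mlr
      }
      stagnating <- !changed && res$gnorm > 0.5 * last_g
      if (stagnating) {
        removed <- FALSE
        if (any(base$nodes$state == "ablated")) {
          mlf <- tryCatch({
            kabl <- which(vapply(base$topo$cells, function(cl)
              base$nodes$state[cl$node] == "ablated", logical(1L)))
            areas <- vapply(kabl, function(k) apical_cell_area(base, k), numeric(1L))
            nd <- base$topo$cells[[kabl[which.min(areas)]]]$node
            m3 <- remove_cell(base, nd)
            m3 <- rebuild_topology(m3)
            if (!is.null(protocol)) maintain_wound(m3, protocol) else m3
          }, error = function(e) NULL)
          if (!is.null(mlf)) {
            base <- mlf
            removed <- TRUE
          }
        }
        if (!removed) dt <- dt / 2
      }
      ml_try <- base
      last_g <- res$gnorm
    }
    ml <- res$ml
    t <- t + dt
    ml$time <- t
    ml <- remesh_step(ml, settings$tol_r)
    if (!is.null(protocol)) ml <- maintain_wound(ml, protocol)
    rows[[length(rows) + 1L]] <- record(ml, t, res$iters, dt)
    if (verbose) {
      r <- rows[[length(rows)]]
      message(sprintf("t=%6.1f  area=%8.2f  h=%5.3f  iters=%d  dt=%.3f",
                      t, r$wound_area_um2, r$rel_height, res$iters, dt))
    }
    if (!is.null(frame_dir)) {
      frame <- frame + 1L
      write_vtk_frame(ml, file.path(frame_dir, sprintf("frame_%04d.vtk", frame)))
    }
    if (stop_at_closure && isTRUE(ml$wound$closed)) break
  }
  finish_sim(rows, ml, params, protocol, settings)
}

finish_sim <- function(rows, ml, params, protocol, settings,
                       aborted = FALSE, t_abort = NA_real_) {
  ts <- dplyr::bind_rows(rows)
  rec_max <- if (any(ts$t_min > 0)) max(ts$wound_area_um2) else NA_real_
  structure(list(
    timeseries = ts,
    monolayer = ml,
    summary = tibble::tibble(
      closed = isTRUE(ml$wound$closed),
      closure_time_min = ml$wound$closure_time,
      recoil_area_um2 = rec_max,
      final_area_um2 = ts$wound_area_um2[nrow(ts)],
      final_rel_height = ts$rel_height[nrow(ts)],
      max_mean_vol_dev = max(ts$mean_vol_dev),
      n_steps = nrow(ts) - 1L,
      aborted = aborted, t_abort_min = t_abort),
    params = params, protocol = protocol, settings = settings),
    class = "epi_sim")
}

#' Apply the homeostatic contractile prestrain
#'
#' Sets viscoelastic rest lengths to L = l/(1+eps_c), the fixed point of the
#' remodeling law, so every vertex segment carries the steady-state tension
#' of the intact contractile tissue. Without it, ablation produces no recoil
#' (the tissue would be born stress-free).
#'
#' @param ml a `monolayer`.
#' @param params [material_params()].
#' @return the prestrained monolayer.
#' @export
prestrain_monolayer <- function(ml, params) {
  l <- segment_lengths(ml)
  eps <- segment_eps_c(ml, params)
  gm <- ml$topo$segments$gamma_on & eps > 0
  ml$topo$segments$L[gm] <- l[gm] / (1 + eps[gm])
  ml$seg_state$L <- ml$topo$segments$L
  ml
}

#' @export
print.epi_sim <- function(x, ...) {
  s <- x$summary
  cat("<epi_sim> ", s$n_steps, " steps",
      if (isTRUE(s$aborted)) " (aborted)" else "", "\n", sep = "")
  cat("  closed: ", s$closed,
      if (isTRUE(s$closed)) paste0(" at t = ", round(s$closure_time_min, 1), " min"),
      "\n", sep = "")
  cat("  recoil area: ", round(s$recoil_area_um2, 2), " um^2",
      "; final area: ", round(s$final_area_um2, 2), " um^2\n", sep = "")
  cat("  final relative height: ", round(s$final_rel_height, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy per-step observables of a simulation
#' @param x an `epi_sim`.
#' @param ... unused.
#' @return the timeseries tibble (one row per converged step).
#' @export
tidy.epi_sim <- function(x, ...) x$timeseries

#' One-row summary of a simulation
#' @param x an `epi_sim`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.epi_sim <- function(x, ...) x$summary

#' Plot wound area and relative height over time
#' @param object an `epi_sim`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.epi_sim <- function(object, ...) {
  ts <- object$timeseries
  df <- tidyr::pivot_longer(
    ts[, c("t_min", "wound_area_um2", "rel_height")],
    cols = c("wound_area_um2", "rel_height"),
    names_to = "observable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          wound_area_um2 = "apical wound area (um^2)",
                          rel_height = "relative height"))) +
    ggplot2::labs(x = "time after ablation (min)", y = NULL)
}

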