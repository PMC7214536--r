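#' Rest-length remodeling rate
#'
#' The viscoelastic law (1/L) dL/dt = gamma * ((l - L)/L - eps_c), i.e.
#' dL/dt = gamma * (l - L (1 + eps_c)): the rest length is stationary exactly
#' when the strain (l - L)/L equals the intrinsic contractility eps_c, and for
#' eps_c = 0 the branch responds like a Maxwell viscous element.
#'
#' @param l current segment length.
#' @param L current rest length (> 0).
#' @param gamma remodeling rate (1/min); 0 gives the purely elastic limit.
#' @param eps_c intrinsic contractility (dimensionless strain).
#' @return dL/dt.
#' @export
rest_length_rate <- function(l, L, gamma, eps_c) {
  if (any(L <= 0)) stop("rest length must be positive")
  gamma * (l - L * (1 + eps_c))
}

# Coefficients of the theta-weighted update written as L_{n+1} = A + B*l_{n+1}:
#   L_{n+1} [1 + dt*gamma*theta*(1+eps_c)] =
#     L_n [1 - dt*gamma*(1-theta)*(1+eps_c)] + dt*gamma*((1-theta) l_n + theta l_{n+1})
theta_coeffs <- function(L_n, l_n, dt, theta, gamma, eps_c) {
  D <- 1 + dt * gamma * theta * (1 + eps_c)
  if (any(D <= 0)) stop("unstable rest-length update: denominator <= 0")
  num0 <- L_n * (1 - dt * gamma * (1 - theta) * (1 + eps_c)) +
    dt * gamma * (1 - theta) * l_n
  list(A = num0 / D, B = dt * gamma * theta / D)
}

#' Theta-weighted rest-length update
#'
#' Solves the linear relation of the implicit theta scheme for the remodeling
#' law and returns L at the end of the step. theta = 0.5 gives a second-order
#' accurate, unconditionally stable scheme; theta = 1 is backward Euler.
#'
#' @param l_n,l_np1 segment length at the start and end of the step.
#' @param L_n rest length at the start of the step (> 0).
#' @param dt time step (min).
#' @param theta weighting in [0, 1] (default 0.5).
#' @param gamma remodeling rate (1/min).
#' @param eps_c intrinsic contractility.
#' @return L at the end of the step.
#' @export
theta_update <- function(l_n, l_np1, L_n, dt, gamma, eps_c, theta = 0.5) {
  if (any(L_n <= 0)) stop("rest length must be positive")
  if (dt <= 0) stop("dt must be positive")
  co <- theta_coeffs(L_n, l_n, dt, theta, gamma, eps_c)
  co$A + co$B * l_np1
}

#' Solver settings
#'
#' @param theta rest-length scheme weight (default 0.5, second order).
#' @param dt_recoil time step during the recoil phase, t <= t_recoil (min).
#' @param dt_closure time step after the recoil phase (min).
#' @param t_recoil end of the recoil phase (min).
#' @param newton_tol convergence tolerance: both the Newton update norm and
#'   the residual norm must drop below it.
#' @param max_newton_iters Newton iteration budget per step.
#' @param max_halvings number of time-step halvings attempted on failure.
#' @param tol_r aspect-ratio tolerance of the remeshing acceptance rule;
#'   0 recovers the standard Delaunay triangulation.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(theta = 0.5, dt_recoil = 0.6, dt_closure = 1.0,
                            t_recoil = 6, newton_tol = 1e-10,
                            max_newton_iters = 80L, max_halvings = 12L,
                            tol_r = 0.1) {
  stopifnot(theta >= 0, theta <= 1, dt_recoil > 0, dt_closure > 0,
            newton_tol > 0, tol_r >= 0)
  structure(list(theta = theta, dt_recoil = dt_recoil, dt_closure = dt_closure,
                 t_recoil = t_recoil, newton_tol = newton_tol,
                 max_newton_iters = as.integer(max_newton_iters),
                 max_halvings = as.integer(max_halvings), tol_r = tol_r),
            class = "solver_settings")
}
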