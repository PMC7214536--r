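#' Material parameters of the monolayer model
#'
#' Defaults are the calibrated recoil-phase values: intrinsic contractility
#' `eps_c = 1.3`, elastic vertex stiffness `k_V0 = 0.05`, remodeling rate
#' `gamma = 0.2` per minute, nodal stiffness `k_N = 0.3`, viscoelastic vertex
#' stiffness `k_V = 1.0`, and volume penalty weight `lambda_Vol = 20` (keeps
#' per-cell relative volume deviations below ~10%). Stiffness units are
#' arbitrary; forces are reported in those units per micrometer.
#'
#' @param k_N nodal segment stiffness (purely elastic; remodeling off).
#' @param k_V viscoelastic-branch vertex segment stiffness.
#' @param k_V0 elastic-branch vertex segment stiffness.
#' @param lambda_Vol quadratic volume penalty weight.
#' @param eps_c intrinsic contractility (dimensionless homeostatic strain).
#' @param gamma rest-length remodeling rate (1/min).
#' @return object of class `material_params`.
#' @export
material_params <- function(k_N = 0.3, k_V = 1.0, k_V0 = 0.05,
                            lambda_Vol = 20, eps_c = 1.3, gamma = 0.2) {
  p <- list(k_N = k_N, k_V = k_V, k_V0 = k_V0, lambda_Vol = lambda_Vol,
            eps_c = eps_c, gamma = gamma)
  if (any(unlist(p) < 0)) stop("material parameters must be non-negative")
  structure(p, class = "material_params")
}

#' Elastic-branch tension of a vertex segment
#'
#' The tension carried by the elastic branch is
#' `sigma_V = k_V0 * (eps_e + Y_hat)` with elastic strain
#' `eps_e = (l - L0)/L0` relative to the segment's birth length and `Y_hat`
#' the scheduled wound-edge contractility (zero away from the wound).
#'
#' @param k_V0 elastic branch stiffness.
#' @param eps_e elastic strain.
#' @param Y_hat active contractility value.
#' @return tension (stiffness units).
#' @export
active_tension <- function(k_V0, eps_e, Y_hat = 0) {
  k_V0 * (eps_e + Y_hat)
}

# Per-segment scalar coefficients for energy evaluation.
# Rest-length law: L_eff = A + B * l. Frozen mode: A = L, B = 0. Implicit
# (theta-weighted) mode: A, B from the discretized remodeling equation, so
# each trial geometry sees rest lengths consistent with itself.
# contract = c(apical, lateral) wound-edge contractility values.
segment_coeffs <- function(ml, params, contract = c(0, 0),
                           rest = c("frozen", "implicit"),
                           dt = NULL, theta = 0.5, l_ref = NULL) {
  rest <- match.arg(rest)
  s <- ml$topo$segments
  nodal <- s$network == "nodal"
  k1 <- ifelse(nodal, params$k_N, params$k_V) * s$scale
  k2 <- ifelse(nodal, 0, params$k_V0) * s$scale
  Y <- contract[1L] * s$wound_apical + contract[2L] * s$wound_lateral
  c_act <- k2 * Y
  if (rest == "frozen") {
    A <- s$L
    B <- rep(0, nrow(s))
  } else {
    if (is.null(dt)) stop("implicit rest-length mode needs dt")
    if (is.null(l_ref)) l_ref <- segment_lengths(ml)
    th <- theta_coeffs(s$L, l_ref, dt, theta, params$gamma, segment_eps_c(ml, params))
    A <- ifelse(s$gamma_on, th$A, s$L)
    B <- ifelse(s$gamma_on, th$B, 0)
  }
  list(k1 = k1, k2 = k2, A = A, B = B, L0 = s$L0, c_act = c_act)
}

# Per-segment contractile set point: the intrinsic contractility eps_c lives
# in the junctional cortex, i.e. the in-plane (apical/basal) vertex segments;
# lateral vertex segments remodel as passive Maxwell elements (eps_c = 0) and
# only carry the scheduled wound-edge contractility.
segment_eps_c <- function(ml, params) {
  s <- ml$topo$segments
  ifelse(s$network == "vertex" & s$orientation %in% c("apical", "basal"),
         params$eps_c, 0)
}

# scalar force f(l) = dW/dl and stiffness df/dl per segment
segment_force <- function(l, co) {
  f <- co$k1 * ((1 - co$B) * l - co$A) * (1 - co$B) +
    co$k2 * (l - co$L0) / co$L0 + co$c_act
  fp <- co$k1 * (1 - co$B)^2 + co$k2 / co$L0
  list(f = f, fp = fp)
}

#' Total energy of the monolayer
#'
#' W = W_N + W_V + W_Vol: nodal springs (k_N/2)(l-L)^2, vertex segments with
#' both the viscoelastic branch (k_V/2)(l-L)^2 (evolving rest length L) and
#' the elastic branch (k_V0/2)(l-L0)^2/L0 plus the active term k_V0*Y_hat*l on
#' scheduled wound-edge segments, and the volume penalty
#' (lambda_Vol/2)((V-V0)/V0)^2 over cells with the penalty active. The
#' stiffness scale of ablated-cell segments multiplies both branches.
#'
#' @param ml a `monolayer`.
#' @param params [material_params()].
#' @param contract length-2 numeric: wound-edge apical and lateral
#'   contractility values (Y_hat_A, Y_hat_L) applied to flagged segments.
#' @param rest `"frozen"` (rest lengths as stored) or `"implicit"` (the
#'   theta-weighted discretization substitutes L(l) before differentiation).
#' @param dt,theta,l_ref time step, theta weight and step-start lengths for
#'   the implicit mode.
#' @param Xd optional trial dof positions (defaults to current state).
#' @return scalar energy.
#' @export
energy_total <- function(ml, params, contract = c(0, 0), rest = "frozen",
                         dt = NULL, theta = 0.5, l_ref = NULL, Xd = NULL) {
  co <- segment_coeffs(ml, params, contract, rest, dt, theta, l_ref)
  if (is.null(Xd)) Xd <- ml_dof_positions(ml)
  Xp <- as.matrix(ml$topo$S %*% Xd)
  l <- segment_lengths(ml, Xp)
  Leff <- co$A + co$B * l
  W_seg <- sum(co$k1 / 2 * (l - Leff)^2 + co$k2 / (2 * co$L0) * (l - co$L0)^2 +
                 co$c_act * l)
  W_seg + volume_energy(ml, params, Xp)
}

volume_energy <- function(ml, params, Xp) {
  pen <- penalized_cells(ml)
  if (!length(pen$rows)) return(0)
  V <- cell_volumes(ml, Xp = Xp)[pen$rows]
  sum(params$lambda_Vol / 2 * ((V - pen$V0) / pen$V0)^2)
}

penalized_cells <- function(ml) {
  cells <- ml$topo$cells
  nd <- vapply(cells, function(cl) cl$node, integer(1L))
  on <- ml$nodes$volume_penalty_on[nd] & !is.na(ml$nodes$V0[nd])
  list(rows = which(on), V0 = ml$nodes$V0[nd[on]])
}

# ---- assembly cache ---------------------------------------------------------

# Precomputed index patterns for gradient/Hessian assembly; valid until the
# topology changes.
build_assembly_cache <- function(ml) {
  topo <- ml$topo
  n_pts <- topo$n_pts
  s <- topo$segments
  ns <- nrow(s)

  # segment Hessian block patterns: blocks (p1,p1),(p2,p2),(p1,p2),(p2,p1),
  # each 3x3 column-major; value vector is c(M, M, -M, -M) with M = n x 9
  a3 <- rep(1:3, times = 3L)  # row coord within block, column-major
  b3 <- rep(1:3, each = 3L)
  block_ij <- function(P, Q) {
    list(i = rep(3L * (P - 1L), each = 9L) + rep(a3, ns),
         j = rep(3L * (Q - 1L), each = 9L) + rep(b3, ns))
  }
  sb <- list(block_ij(s$p1, s$p1), block_ij(s$p2, s$p2),
             block_ij(s$p1, s$p2), block_ij(s$p2, s$p1))
  seg_i <- unlist(lapply(sb, `[[`, "i"))
  seg_j <- unlist(lapply(sb, `[[`, "j"))

  # volume: per-cell point lists and slot maps
  tets <- topo$tets
  nt <- nrow(tets)
  tc <- topo$tet_cell
  pen <- penalized_cells(ml)
  pen_rows <- pen$rows
  keep_t <- tc %in% pen_rows
  tets_p <- tets[keep_t, , drop = FALSE]
  tc_p <- tc[keep_t]
  cell_pts <- lapply(pen_rows, function(k) sort(unique(as.integer(tets_p[tc_p == k, ]))))
  names(cell_pts) <- as.character(pen_rows)
  # slot of each (cell, point): offsets into the concatenated per-cell list
  len <- lengths(cell_pts)
  off <- c(0L, cumsum(len))[seq_along(len)]
  cell_of <- match(tc_p, pen_rows)
  slot <- matrix(0L, nrow(tets_p), 4L)
  for (ccol in 1:4) {
    slot[, ccol] <- off[cell_of] +
      vapply(seq_len(nrow(tets_p)), function(r)
        match(tets_p[r, ccol], cell_pts[[cell_of[r]]]), integer(1L))
  }
  # outer-product triplet patterns per cell: (3*len)^2 entries
  vo <- lapply(seq_along(pen_rows), function(kk) {
    pts <- cell_pts[[kk]]
    cr <- as.vector(t(outer(3L * (pts - 1L), 1:3, "+")))    # global coords
    lc <- off[kk] * 3L + seq_len(3L * length(pts))          # local grad coords
    grid_i <- rep(cr, times = length(cr))
    grid_j <- rep(cr, each = length(cr))
    ga <- rep(lc, times = length(lc))
    gb <- rep(lc, each = length(lc))
    list(i = grid_i, j = grid_j, ga = ga, gb = gb,
         cell = rep(kk, length(grid_i)))
  })
  vol_i <- unlist(lapply(vo, `[[`, "i"))
  vol_j <- unlist(lapply(vo, `[[`, "j"))
  vol_ga <- unlist(lapply(vo, `[[`, "ga"))
  vol_gb <- unlist(lapply(vo, `[[`, "gb"))
  vol_cell <- unlist(lapply(vo, `[[`, "cell"))

  # curvature (second derivative of V) block patterns: 12 ordered pairs (a,b),
  # a != b, block = skew(e_ab)/6 with pair edge vectors defined below
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  skew_rows <- c(2L, 3L, 1L, 3L, 1L, 2L)  # nonzero entries of skew(v), column-major
  skew_cols <- c(1L, 1L, 2L, 2L, 3L, 3L)
  skew_sign <- c(1, -1, -1, 1, 1, -1)      # times v3, v2, v3, v1, v2, v1
  skew_comp <- c(3L, 2L, 3L, 1L, 2L, 1L)
  cur_i <- integer(0); cur_j <- integer(0)
  cur_pair <- integer(0); cur_comp <- integer(0); cur_sign <- numeric(0)
  cur_tet <- integer(0)
  ntp <- nrow(tets_p)
  for (pr in seq_len(6L)) {
    a <- pairs[pr, 1L]; b <- pairs[pr, 2L]
    Pa <- tets_p[, a]; Pb <- tets_p[, b]
    # block (a,b): skew(e)/6 ; block (b,a): -skew(e)/6 transposed = skew(-e)/6^T
    for (kk in seq_len(6L)) {
      cur_i <- c(cur_i, 3L * (Pa - 1L) + skew_rows[kk], 3L * (Pb - 1L) + skew_cols[kk])
      cur_j <- c(cur_j, 3L * (Pb - 1L) + skew_cols[kk], 3L * (Pa - 1L) + skew_rows[kk])
      cur_pair <- c(cur_pair, rep(pr, 2L * ntp))
      cur_comp <- c(cur_comp, rep(skew_comp[kk], 2L * ntp))
      cur_sign <- c(cur_sign, rep(skew_sign[kk], ntp), rep(skew_sign[kk], ntp))
      cur_tet <- c(cur_tet, rep(seq_len(ntp), 2L))
    }
  }

  free <- !topo$fixed_dof_pts
  free_coords <- as.vector(t(outer(3L * (which(free) - 1L), 1:3, "+")))
  S3 <- Matrix::kronecker(topo$S, Matrix::Diagonal(3L))
  P <- S3[, free_coords, drop = FALSE]

  list(seg_i = seg_i, seg_j = seg_j,
       tets_p = tets_p, tc_p = tc_p, cell_of = cell_of, slot = slot,
       cell_pts = cell_pts, pen_rows = pen_rows, pen_V0 = pen$V0,
       n_slots = sum(len),
       vol_i = vol_i, vol_j = vol_j, vol_ga = vol_ga, vol_gb = vol_gb,
       vol_cell = vol_cell,
       cur_i = cur_i, cur_j = cur_j, cur_pair = cur_pair, cur_comp = cur_comp,
       cur_sign = cur_sign, cur_tet = cur_tet, pairs = pairs,
       free_coords = free_coords, S3 = S3, P = P, n_pts = n_pts)
}

get_cache <- function(ml) {
  if (is.null(ml$cache)) build_assembly_cache(ml) else ml$cache
}

# ---- gradient and Hessian in point space ------------------------------------

# gradient of total energy w.r.t. all point coordinates (n_pts x 3), plus
# per-tet corner gradients of V (needed for the Hessian outer products)
assemble_gradient <- function(ml, params, co, Xp, cache, want_vol_grads = FALSE) {
  topo <- ml$topo
  s <- topo$segments
  d <- Xp[s$p2, , drop = FALSE] - Xp[s$p1, , drop = FALSE]
  l <- sqrt(rowSums(d^2))
  tvec <- d / l
  fr <- segment_force(l, co)
  G <- matrix(0, topo$n_pts, 3L)
  contrib <- rowsum(rbind(-fr$f * tvec, fr$f * tvec), c(s$p1, s$p2))
  rows <- as.integer(rownames(contrib))
  G[rows, ] <- G[rows, ] + contrib

  # volume term
  out <- list(l = l, tvec = tvec, f = fr$f, fp = fr$fp)
  tp <- cache$tets_p
  if (nrow(tp)) {
    t1 <- Xp[tp[, 1L], , drop = FALSE]; t2 <- Xp[tp[, 2L], , drop = FALSE]
    t3 <- Xp[tp[, 3L], , drop = FALSE]; t4 <- Xp[tp[, 4L], , drop = FALSE]
    u <- t2 - t1; v <- t3 - t1; w <- t4 - t1
    g2 <- cross3(v, w) / 6; g3 <- cross3(w, u) / 6; g4 <- cross3(u, v) / 6
    g1 <- -(g2 + g3 + g4)
    v6 <- rowSums(u * cross3(v, w))
    Vc <- as.numeric(rowsum(v6, cache$cell_of)) / 6
    V0 <- cache$pen_V0
    q <- params$lambda_Vol * (Vc - V0) / V0^2
    qt <- q[cache$cell_of]
    corner_g <- rbind(g1, g2, g3, g4)
    corner_pt <- c(tp[, 1L], tp[, 2L], tp[, 3L], tp[, 4L])
    contrib <- rowsum(qt * corner_g, corner_pt)
    rows <- as.integer(rownames(contrib))
    G[rows, ] <- G[rows, ] + contrib
    if (want_vol_grads) {
      out$corner_g <- corner_g
      out$q <- q
      out$Vc <- Vc
      out$V0 <- V0
      out$tet_pts <- list(t1 = t1, t2 = t2, t3 = t3, t4 = t4)
    }
  }
  out$G <- G
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Hessian of total energy w.r.t. point coordinates (sparse, 3 n_pts square)
assemble_hessian <- function(ml, params, co, Xp, cache, grad) {
  topo <- ml$topo
  ns <- nrow(topo$segments)
  tvec <- grad$tvec
  T9 <- matrix(0, ns, 9L)
  idx <- 0L
  for (b in 1:3) for (a in 1:3) {
    idx <- idx + 1L
    T9[, idx] <- tvec[, a] * tvec[, b]
  }
  I9 <- as.numeric(diag(3))
  M <- grad$fp * T9 + (grad$f / grad$l) * (matrix(I9, ns, 9L, byrow = TRUE) - T9)
  # patterns are block-major with each segment's 9 entries contiguous
  Mt <- as.numeric(t(M))
  i_all <- cache$seg_i; j_all <- cache$seg_j
  x_all <- c(Mt, Mt, -Mt, -Mt)

  if (nrow(cache$tets_p)) {
    # outer products: lambda/V0^2 * gVc gVc^T per cell
    slot_g <- rowsum(grad$corner_g, as.integer(cache$slot))
    g_flat <- as.numeric(t(slot_g))  # (x,y,z) per slot
    wcell <- params$lambda_Vol / grad$V0^2
    x_vol <- g_flat[cache$vol_ga] * g_flat[cache$vol_gb] * wcell[cache$vol_cell]
    # curvature: q_c * skew(e_ab)/6 blocks
    tp <- grad$tet_pts
    e <- list(tp$t3 - tp$t4, tp$t4 - tp$t2, tp$t2 - tp$t3,
              tp$t1 - tp$t4, tp$t3 - tp$t1, tp$t1 - tp$t2)
    qt <- grad$q[cache$cell_of] / 6
    ecomp <- vapply(1:6, function(pr) e[[pr]], e[[1L]])  # ntp x 3 x 6
    x_cur <- cur_values(cache, ecomp, qt)
    i_all <- c(i_all, cache$vol_i, cache$cur_i)
    j_all <- c(j_all, cache$vol_j, cache$cur_j)
    x_all <- c(x_all, x_vol, x_cur)
  }
  Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all,
                       dims = c(3L * topo$n_pts, 3L * topo$n_pts))
}

cur_values <- function(cache, ecomp, qt) {
  # ecomp: ntp x 3 x 6 edge vectors; entries follow cache$cur_* patterns
  v <- ecomp[cbind(cache$cur_tet, cache$cur_comp, cache$cur_pair)]
  v * cache$cur_sign * qt[cache$cur_tet]
}

# ---- public residual / jacobian --------------------------------------------

#' Residual of mechanical equilibrium
#'
#' Assembles the energy gradient with respect to node positions (apical and
#' basal cell centers) and free vertices, applying the barycentric chain rule
#' (each constrained vertex contributes 1/3 of its force to each parent node)
#' and reporting zero rows for fixed (Dirichlet) nodes.
#'
#' @inheritParams energy_total
#' @return list with `forces` (n_dof x 3 matrix), `norm` (2-norm over free
#'   coordinates) and the free-coordinate vector `g`.
#' @export
residual <- function(ml, params, contract = c(0, 0), rest = "frozen",
                     dt = NULL, theta = 0.5, l_ref = NULL, Xd = NULL) {
  co <- segment_coeffs(ml, params, contract, rest, dt, theta, l_ref)
  cache <- get_cache(ml)
  if (is.null(Xd)) Xd <- ml_dof_positions(ml)
  Xp <- as.matrix(ml$topo$S %*% Xd)
  gr <- assemble_gradient(ml, params, co, Xp, cache)
  if (any(!is.finite(gr$G))) {
    bad <- which(!is.finite(rowSums(gr$G)))[1L]
    stop("non-finite force at point ", bad, " during residual assembly")
  }
  Gd <- as.matrix(Matrix::crossprod(ml$topo$S, gr$G))
  Gd[ml$topo$fixed_dof_pts, ] <- 0
  g <- as.numeric(t(Gd))[cache$free_coords]
  structure(list(forces = Gd, g = g, norm = sqrt(sum(g^2))), class = "ml_residual")
}

#' Tangent (Jacobian) of the residual
#'
#' Analytic second derivative of the total energy, reduced to the free
#' degrees of freedom by the interpolation map (Dirichlet elimination).
#'
#' @inheritParams energy_total
#' @param reduced if `TRUE` (default) return the free-coordinate operator used
#'   by the solver; otherwise the full dof-space operator with fixed
#'   rows/columns zeroed.
#' @return sparse symmetric matrix.
#' @export
jacobian <- function(ml, params, contract = c(0, 0), rest = "frozen",
                     dt = NULL, theta = 0.5, l_ref = NULL, Xd = NULL,
                     reduced = TRUE) {
  co <- segment_coeffs(ml, params, contract, rest, dt, theta, l_ref)
  cache <- get_cache(ml)
  if (is.null(Xd)) Xd <- ml_dof_positions(ml)
  Xp <- as.matrix(ml$topo$S %*% Xd)
  gr <- assemble_gradient(ml, params, co, Xp, cache, want_vol_grads = TRUE)
  H <- assemble_hessian(ml, params, co, Xp, cache, gr)
  if (reduced) {
    Matrix::crossprod(cache$P, H %*% cache$P)
  } else {
    S3 <- cache$S3
    Hd <- Matrix::crossprod(S3, H %*% S3)
    fixed <- which(ml$topo$fixed_dof_pts)
    if (length(fixed)) {
      fc <- as.vector(t(outer(3L * (fixed - 1L), 1:3, "+")))
      Hd[fc, ] <- 0
      Hd[, fc] <- 0
    }
    Hd
  }
}
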