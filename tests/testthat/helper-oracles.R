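# independent oracles used by the tests

# scipy Delaunay triangulation (independent of the package's Bowyer-Watson)
scipy_delaunay <- function(xy) {
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  utils::write.table(xy, fin, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(
    "import numpy as np; from scipy.spatial import Delaunay; pts = np.loadtxt('%s', delimiter=','); np.savetxt('%s', np.sort(Delaunay(pts).simplices + 1, axis=1), fmt='%%d', delimiter=',')",
    fin, fout)
  status <- system2("python", c("-c", shQuote(code)))
  stopifnot(status == 0)
  tri <- as.matrix(utils::read.csv(fout, header = FALSE))
  tri[order(tri[, 1], tri[, 2], tri[, 3]), , drop = FALSE]
}

# convex hull volume (scipy) for convex prism-like cells
scipy_hull_volume <- function(pts) {
  fin <- tempfile(fileext = ".csv")
  utils::write.table(pts, fin, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(
    "import numpy as np; from scipy.spatial import ConvexHull; print(ConvexHull(np.loadtxt('%s', delimiter=',')).volume)",
    fin)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  as.numeric(out[length(out)])
}

sorted_triangles <- function(tri) {
  s <- t(apply(tri, 1, sort))
  s[order(s[, 1], s[, 2], s[, 3]), , drop = FALSE]
}

# central-difference gradient of the energy w.r.t. selected free coordinates
fd_gradient <- function(ml, params, sel, h = 1e-6, ...) {
  Xd <- ml_dof_positions(ml)
  cache <- epiwound3d:::get_cache(ml)
  idx <- cache$free_coords
  vapply(sel, function(k) {
    c_ <- idx[k]; pt <- (c_ - 1) %/% 3 + 1; co <- (c_ - 1) %% 3 + 1
    X1 <- Xd; X1[pt, co] <- X1[pt, co] + h
    X2 <- Xd; X2[pt, co] <- X2[pt, co] - h
    (energy_total(ml, params, Xd = X1, ...) -
       energy_total(ml, params, Xd = X2, ...)) / (2 * h)
  }, numeric(1))
}

# brute-force mesh validator: barycentric exactness of constrained vertices
# and two-sided sharing of interior lateral surface triangles
validate_mesh <- function(ml) {
  Xp <- ml_points(ml)
  v <- ml$topo$verts
  con <- v[v$kind == "constrained", ]
  for (k in seq_len(nrow(con))) {
    tri <- if (con$layer[k] == "a") ml$tri_a else ml$tri_b
    X <- if (con$layer[k] == "a") ml$xa else ml$xb
    bc <- colMeans(X[tri[con$tri_row[k], ], , drop = FALSE])
    if (max(abs(Xp[con$point[k], ] - bc)) > 1e-12) {
      return(paste("vertex", con$key[k], "not barycentric"))
    }
  }
  tt <- ml$topo$tets
  nodepts <- 2L * ml$topo$n_act
  iscap <- tt[, 2] <= nodepts | tt[, 3] <= nodepts | tt[, 4] <= nodepts
  key <- apply(tt[!iscap, 2:4, drop = FALSE], 1, function(r) paste(sort(r), collapse = "-"))
  counts <- table(key)
  if (any(counts > 2)) return("lateral face triangle shared by more than two cells")
  TRUE
}

# explicit fine-step integration of the rest-length evolution law
ode_rest_length <- function(l_fun, L0, t_end, gamma, eps_c, dt = 1e-4) {
  t <- 0; L <- L0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- gamma * (l_fun(t) - L * (1 + eps_c))
    k2 <- gamma * (l_fun(t + h / 2) - (L + h / 2 * k1) * (1 + eps_c))
    k3 <- gamma * (l_fun(t + h / 2) - (L + h / 2 * k2) * (1 + eps_c))
    k4 <- gamma * (l_fun(t + h) - (L + h * k3) * (1 + eps_c))
    L <- L + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  L
}
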