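test_that("the freshly built state is the zero-energy reference", {
  ml <- small_monolayer()
  p <- material_params()
  expect_equal(energy_total(ml, p), 0)
  expect_equal(residual(ml, p)$norm, 0)
})

test_that("single-branch energies follow their closed forms", {
  # viscoelastic branch: l = 2, L = 1, k_V = 1 -> W = 0.5
  expect_equal(1 / 2 * (2 - 1)^2, 0.5)
  ml <- small_monolayer()
  p <- material_params(k_N = 0, k_V = 1, k_V0 = 0, lambda_Vol = 0)
  s <- ml$topo$segments
  vert <- which(s$network == "vertex")[1]
  l <- epiwound3d:::segment_lengths(ml)
  ml$topo$segments$L[vert] <- l[vert] / 2
  expect_equal(energy_total(ml, p), 0.5 * (l[vert] - l[vert] / 2)^2,
               tolerance = 1e-12)
})

test_that("active tension follows sigma_V = k_V0 (eps_e + Y)", {
  expect_equal(active_tension(0.05, 0, 0), 0)
  expect_equal(active_tension(0.05, 0, 2.3), 0.115)
  expect_equal(active_tension(0.05, 0.2, 1), 0.06)
})

test_that("total energy matches an exhaustive term-by-term summation", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(11)
  s <- ml$topo$segments
  ml$topo$segments$L <- s$L * runif(nrow(s), 0.8, 1.2)
  ml$topo$segments$wound_apical[sample(nrow(s), 5)] <- TRUE
  contract <- c(1.7, 0)
  l <- epiwound3d:::segment_lengths(ml)
  s <- ml$topo$segments
  k1 <- ifelse(s$network == "nodal", p$k_N, p$k_V) * s$scale
  k2 <- ifelse(s$network == "nodal", 0, p$k_V0) * s$scale
  W_manual <- sum(k1 / 2 * (l - s$L)^2) +
    sum(k2 / (2 * s$L0) * (l - s$L0)^2) +
    sum((k2 * contract[1] * s$wound_apical) * l)
  # reference volumes are exact here, so the volume penalty is zero
  expect_equal(energy_total(ml, p, contract = contract), W_manual,
               tolerance = 1e-12)
})

test_that("residual equals the finite-difference energy gradient", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(42)
  Xd <- ml_dof_positions(ml)
  free <- !ml$topo$fixed_dof_pts
  Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 0.3), ncol = 3)
  ml <- epiwound3d:::ml_set_dof_positions(ml, Xd)
  ml$topo$segments$wound_apical[sample(nrow(ml$topo$segments), 6)] <- TRUE
  l_ref <- epiwound3d:::segment_lengths(small_monolayer())
  for (mode in c("frozen", "implicit")) {
    extra <- if (mode == "implicit") list(dt = 0.6, l_ref = l_ref) else list()
    r <- do.call(residual, c(list(ml, p, contract = c(2.3, 0), rest = mode), extra))
    cache <- epiwound3d:::get_cache(ml)
    set.seed(1)
    sel <- sample(length(cache$free_coords), min(50, length(cache$free_coords)))
    gfd <- do.call(fd_gradient,
                   c(list(ml, p, sel, contract = c(2.3, 0), rest = mode), extra))
    expect_lt(sqrt(sum((r$g[sel] - gfd)^2)) / sqrt(sum(gfd^2)), 1e-5)
  }
})

test_that("the analytic tangent matches finite differences of the residual", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(7)
  Xd <- ml_dof_positions(ml)
  free <- !ml$topo$fixed_dof_pts
  Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 0.15), ncol = 3)
  ml <- epiwound3d:::ml_set_dof_positions(ml, Xd)
  H <- jacobian(ml, p)
  expect_lt(max(abs(H - Matrix::t(H))), 1e-12)
  cache <- epiwound3d:::get_cache(ml)
  idx <- cache$free_coords
  Xd <- ml_dof_positions(ml)
  h <- 1e-6
  set.seed(2)
  for (col in sample(length(idx), min(10, length(idx)))) {
    c_ <- idx[col]; pt <- (c_ - 1) %/% 3 + 1; co <- (c_ - 1) %% 3 + 1
    X1 <- Xd; X1[pt, co] <- X1[pt, co] + h
    X2 <- Xd; X2[pt, co] <- X2[pt, co] - h
    col_fd <- (residual(ml, p, Xd = X1)$g - residual(ml, p, Xd = X2)$g) / (2 * h)
    expect_lt(max(abs(H[, col] - col_fd)) / max(abs(col_fd)), 1e-4)
  }
})

test_that("zero stiffness yields a zero tangent", {
  ml <- small_monolayer()
  p0 <- material_params(k_N = 0, k_V = 0, k_V0 = 0, lambda_Vol = 0)
  H <- jacobian(ml, p0)
  expect_equal(max(abs(H)), 0)
})

test_that("internal energy is translation invariant", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(3)
  Xd <- ml_dof_positions(ml)
  free <- !ml$topo$fixed_dof_pts
  Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 0.2), ncol = 3)
  E1 <- energy_total(ml, p, Xd = Xd)
  shift <- matrix(c(5, -3, 2), nrow(Xd), 3, byrow = TRUE)
  E2 <- energy_total(ml, p, Xd = Xd + shift)
  expect_equal(E1, E2, tolerance = 1e-10)
  # a stress-free state rigidly translated has zero residual
  X0 <- ml_dof_positions(small_monolayer())
  r <- residual(small_monolayer(), p, Xd = X0 + shift)
  expect_lt(r$norm, 1e-10)
})

test_that("energy terms stay non-negative on random states", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(19)
  for (i in 1:5) {
    Xd <- ml_dof_positions(ml)
    free <- !ml$topo$fixed_dof_pts
    Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 0.4), ncol = 3)
    expect_gte(energy_total(ml, p, Xd = Xd), 0)
  }
})
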