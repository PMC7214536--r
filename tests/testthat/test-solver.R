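test_that("starting at equilibrium takes zero Newton iterations", {
  ml <- small_monolayer()  # stress-free reference state
  res <- newton_solve(ml, material_params())
  expect_equal(res$iters, 0L)
  expect_true(res$converged)
})

test_that("a single free node on near-zero-rest-length springs finds the analytic minimizer", {
  ml <- build_monolayer(rosette_centers(spacing = 2), height = 2)
  cen <- rosette_centers(spacing = 2)
  central <- cen$cell_id[which.min(cen$x_um^2 + cen$y_um^2)]
  ml$nodes$is_fixed <- TRUE
  ml$nodes$is_fixed[central] <- FALSE
  ml <- rebuild_topology(ml)
  # basal twin fixed too: fix it by fixing... the node flag covers both layers,
  # so instead only the apical point should move: emulate by symmetry (the
  # basal point sees the mirrored problem and lands at the mirrored optimum)
  ml$topo$segments$L <- rep(1e-12, nrow(ml$topo$segments))
  ml$seg_state$L <- ml$topo$segments$L
  p <- material_params(k_N = 0.3, k_V = 0, k_V0 = 0, lambda_Vol = 0)
  # perturb the free node
  ml$xa[central, ] <- ml$xa[central, ] + c(0.3, -0.2, 0.1)
  ml$xb[central, ] <- ml$xb[central, ] + c(-0.1, 0.2, -0.3)
  res <- newton_solve(ml, p, settings = solver_settings())
  expect_true(res$converged)
  # with all-equal stiffness zero-rest-length springs, the minimizer is the
  # mean of the connected (fixed) endpoints
  s <- res$ml$topo$segments
  Xp <- ml_points(res$ml)
  row_a <- res$ml$topo$node_row[central]
  for (row in c(row_a, row_a + res$ml$topo$n_act)) {
    nb <- c(s$p2[s$p1 == row], s$p1[s$p2 == row])
    expect_equal(unname(Xp[row, ]), unname(colMeans(Xp[nb, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("Newton reaches the stated tolerance on a perturbed patch", {
  ml <- small_monolayer()
  p <- material_params()
  set.seed(21)
  Xd <- ml_dof_positions(ml)
  free <- !ml$topo$fixed_dof_pts
  Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 0.1), ncol = 3)
  ml <- epiwound3d:::ml_set_dof_positions(ml, Xd)
  res <- newton_solve(ml, p)
  expect_true(res$converged)
  expect_lte(res$gnorm, 1e-10)
})

test_that("an unwounded homeostatic patch settles without drift", {
  # after the prestrained settle, rest-length rates are near their fixed
  # point: the per-step displacement is tiny and decays
  cen <- generate_hex_patch(patch_spec(37, spacing = 12, noise_amplitude = 0))
  p <- material_params()
  set <- solver_settings()
  ml <- build_monolayer(cen, height = 35, length_scale = 35)
  ml <- prestrain_monolayer(ml, p)
  ml <- newton_solve(ml, p, settings = set)$ml
  d <- numeric(3)
  for (k in 1:3) {
    X0 <- ml_dof_positions(ml)
    ml <- newton_solve(ml, p, t = k * 0.6, dt = 0.6, settings = set)$ml
    d[k] <- max(abs(ml_dof_positions(ml) - X0))
  }
  expect_lt(d[1], 1e-2)
  expect_lt(d[3], d[1])
})

test_that("simulations are deterministic for fixed inputs", {
  cen <- make_centers(30, seed = 13)
  abl <- select_ablation_region(cen, 2)
  prot <- wound_protocol(abl, Y_Ac = 2.3)
  run <- function() run_simulation(cen, material_params(), prot,
                                   solver_settings(), t_end = 2.4)
  s1 <- run(); s2 <- run()
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(glance(s1), glance(s2))
  expect_s3_class(tidy(s1), "tbl_df")
  expect_s3_class(autoplot(s1), "ggplot")
})
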