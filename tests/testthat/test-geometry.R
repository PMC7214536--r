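test_that("the central rosette cell is a hexagonal prism", {
  ml <- fixture("rosette_ml", build_monolayer(rosette_centers(), height = 35))
  cen <- rosette_centers()
  central <- cen$cell_id[which.min(cen$x_um^2 + cen$y_um^2)]
  cl <- ml$topo$cells[[as.character(central)]]
  expect_length(cl$loop_a, 6L)
  expect_length(cl$loop_b, 6L)
})

test_that("constrained vertices sit exactly at parent-triangle barycenters", {
  ml <- small_monolayer()
  Xp <- ml_points(ml)
  v <- ml$topo$verts
  con <- v[v$kind == "constrained" & v$layer == "a", ]
  bc <- t(vapply(seq_len(nrow(con)), function(k)
    colMeans(ml$xa[ml$tri_a[con$tri_row[k], ], ]), numeric(3)))
  expect_lt(max(abs(Xp[con$point, ] - bc)), 1e-13)
  # interpolate_vertices reports the same positions
  iv <- interpolate_vertices(ml)
  expect_equal(unname(as.matrix(iv[match(con$key, iv$key), c("x", "y", "z")])),
               unname(bc), tolerance = 1e-13)
})

test_that("vertex interpolation is affinely equivariant", {
  ml <- small_monolayer()
  t_vec <- c(3.2, -1.7, 0.4)
  ml2 <- ml
  ml2$xa <- sweep(ml2$xa, 2, -t_vec)
  ml2$xb <- sweep(ml2$xb, 2, -t_vec)
  if (nrow(ml2$free_verts)) {
    ml2$free_verts[, c("x", "y", "z")] <-
      sweep(as.matrix(ml2$free_verts[, c("x", "y", "z")]), 2, -t_vec)
  }
  d <- ml_points(ml2) - ml_points(ml)
  expect_equal(unname(d), matrix(t_vec, nrow(d), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("every interior lateral face is shared by exactly two cells", {
  ml <- small_monolayer()
  expect_true(isTRUE(validate_mesh(ml)))
})

test_that("a unit-square prism cell has volume 1", {
  # 5 x 5 square lattice, spacing 1, height 1: interior cells are unit cubes
  g <- expand.grid(x_um = 0:4, y_um = 0:4)
  cen <- tibble::tibble(cell_id = seq_len(nrow(g)), x_um = g$x_um, y_um = g$y_um)
  ml <- build_monolayer(cen, height = 1)
  central <- cen$cell_id[cen$x_um == 2 & cen$y_um == 2]
  expect_equal(cell_volume(ml, central), 1, tolerance = 1e-12)
})

test_that("a regular hexagonal prism matches 3*sqrt(3) and the hull oracle", {
  # rosette with spacing sqrt(3): hexagon side 1; height 2
  cen <- generate_hex_patch(patch_spec(7, spacing = sqrt(3), noise_amplitude = 0))
  ml <- build_monolayer(cen, height = 2)
  central <- cen$cell_id[which.min(cen$x_um^2 + cen$y_um^2)]
  v <- cell_volume(ml, central)
  expect_equal(v, 3 * sqrt(3), tolerance = 1e-9)
  cl <- ml$topo$cells[[as.character(central)]]
  Xp <- ml_points(ml)
  pts <- Xp[c(cl$loop_a, cl$loop_b), ]
  expect_equal(v, scipy_hull_volume(pts), tolerance = 1e-9)
})

test_that("cell volumes agree with the convex-hull oracle on a jittered patch", {
  ml <- fixture("ml48", build_monolayer(make_centers(48, seed = 8)))
  Xp <- ml_points(ml)
  vols <- cell_volumes(ml)
  for (k in c(1, 10, 25)) {
    cl <- ml$topo$cells[[k]]
    pts <- Xp[c(cl$loop_a, cl$loop_b,
                ml$topo$node_row[cl$node],
                ml$topo$node_row[cl$node] + ml$topo$n_act), ]
    expect_equal(unname(vols[k]), scipy_hull_volume(pts), tolerance = 1e-9)
  }
})

test_that("cell volumes tile the monolayer slab", {
  cen <- generate_hex_patch(patch_spec(37, spacing = 12, noise_amplitude = 0))
  ml <- build_monolayer(cen, height = 35)
  Xp <- ml_points(ml)
  areas <- sapply(seq_along(ml$topo$cells), function(k)
    epiwound3d:::apical_cell_area(ml, k, Xp))
  expect_equal(sum(cell_volumes(ml)), sum(areas) * 35, tolerance = 1e-9)
})

test_that("degenerate zero-height cells are flagged", {
  g <- expand.grid(x_um = 0:4, y_um = 0:4)
  cen <- tibble::tibble(cell_id = seq_len(nrow(g)), x_um = g$x_um, y_um = g$y_um)
  ml <- build_monolayer(cen, height = 1)
  central <- cen$cell_id[cen$x_um == 2 & cen$y_um == 2]
  # collapse the cell onto the basal plane
  ml$xa[, 3] <- 0
  expect_equal(cell_volume(ml, central), 0, tolerance = 1e-12)
  expect_error(cell_volume(ml, central, check = TRUE), "volume")
})

test_that("triangle aspect ratio follows the longest/shortest edge rule", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(triangle_aspect_ratio(eq), 1, tolerance = 1e-12)
  iso <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(triangle_aspect_ratio(iso), sqrt(2), tolerance = 1e-12)
  # sliver with edge lengths 1, 1, 1.999
  x <- 1.999 / 2
  h <- sqrt(1 - x^2)
  sl <- rbind(c(0, 0), c(1.999, 0), c(x, h))
  expect_equal(triangle_aspect_ratio(sl), 1.999, tolerance = 1e-9)
  expect_equal(triangle_aspect_ratio(rbind(c(0, 0), c(0, 0), c(1, 0))), Inf)
})
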