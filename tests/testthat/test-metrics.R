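test_that("shoelace areas of canonical polygons are exact", {
  sq <- epiwound3d:::shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(sq, 1)
  th <- 2 * pi * (0:5) / 6
  hexa <- epiwound3d:::shoelace_area(cos(th), sin(th))
  expect_equal(hexa, 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("a closed or unwounded monolayer reports zero wound area", {
  ml <- small_monolayer()
  expect_equal(apical_wound_area(ml), 0)
  expect_equal(unname(wound_edge_counts(ml)), c(0L, 0L))
  std <- std_patch()
  ml2 <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  ml2$wound$closed <- TRUE
  expect_equal(apical_wound_area(ml2), 0)
  expect_equal(unname(wound_edge_counts(ml2)), c(0L, 0L))
})

test_that("relative height is 1 for a flat monolayer and tracks imposed depth", {
  ml <- small_monolayer()
  expect_equal(relative_height(ml), 1)
  std <- std_patch()
  ml2 <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  expect_equal(relative_height(ml2, 35), 1, tolerance = 1e-6)
  # depress the wound perimeter by 7 um (0.2 height units): 1 - 7/35 = 0.8
  pv <- unique(unlist(ml2$topo$perimeter$cycles))
  free_rows <- 2 * ml2$topo$n_act + seq_len(nrow(ml2$free_verts))
  depress <- intersect(pv, free_rows)
  ml2$free_verts$z[match(depress, free_rows)] <-
    ml2$free_verts$z[match(depress, free_rows)] - 0.2
  # constrained perimeter vertices (if any) follow their nodes; depress those
  # nodes' apical z as well so the whole perimeter sits 7 um lower
  con_pv <- setdiff(pv, free_rows)
  if (length(con_pv)) {
    v <- ml2$topo$verts
    for (p in con_pv) {
      tr <- ml2$tri_a[v$tri_row[v$point == p & v$layer == "a"], ]
      ml2$xa[tr, 3] <- 1 - 0.2
    }
  }
  expect_equal(relative_height(ml2, 35), 0.8, tolerance = 0.02)
})

test_that("volume deviation statistics are exact arithmetic over alive cells", {
  ml <- small_monolayer()
  expect_equal(unname(volume_deviation_stats(ml)), c(0, 0), tolerance = 1e-12)
  # impose V/V0 = 1.05 and 0.92 on two cells
  nd <- sapply(ml$topo$cells, `[[`, "node")
  V <- cell_volumes(ml)
  ml$nodes$V0[nd[1]] <- V[[1]] / 1.05
  ml$nodes$V0[nd[2]] <- V[[2]] / 0.92
  dev <- abs(V - ml$nodes$V0[nd]) / ml$nodes$V0[nd]
  st <- volume_deviation_stats(ml)
  expect_equal(unname(st["mean"]), mean(dev), tolerance = 1e-12)
  expect_equal(unname(st["max"]), max(dev), tolerance = 1e-12)
  expect_equal(unname(st["max"]), 0.08, tolerance = 1e-9)
  # ablated cells are excluded from the statistics
  ml$nodes$state[nd[1]] <- "ablated"
  st2 <- volume_deviation_stats(ml)
  expect_equal(unname(st2["max"]), 0.08, tolerance = 1e-9)
  expect_lt(st2[["mean"]], st[["mean"]] + 1e-12)
})

test_that("the area metric is invariant under in-plane rigid motions", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  a0 <- apical_wound_area(ml)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(X) cbind(X[, 1:2] %*% R + matrix(c(3, -2), nrow(X), 2, byrow = TRUE), X[, 3])
  ml$xa <- rot(ml$xa); ml$xb <- rot(ml$xb)
  fv <- as.matrix(ml$free_verts[, c("x", "y", "z")])
  ml$free_verts[, c("x", "y", "z")] <- as.data.frame(rot(fv))
  expect_equal(apical_wound_area(ml), a0, tolerance = 1e-9)
})
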