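test_that("an already-Delaunay configuration is a flip fixed point", {
  set.seed(5)
  xy <- matrix(runif(60, 0, 10), ncol = 2)
  tri <- delaunay_triangulate(xy)
  out <- propose_flips(tri, xy, tol_r = 0)
  expect_equal(sorted_triangles(out), sorted_triangles(tri))
})

test_that("tol_r = 0 recovers the exact Delaunay triangulation after motion", {
  # interior points move (as between simulation steps); hull points stay
  # fixed so the triangulated domain is unchanged, and the start
  # triangulation must remain geometrically valid (no inverted triangles)
  for (s in c(3, 12)) {
    set.seed(s)
    xy <- matrix(runif(80, 0, 10), ncol = 2)
    tri <- delaunay_triangulate(xy)
    et <- epiwound3d:::tri_edge_table(tri)
    hull <- unique(c(et$i[is.na(et$t2)], et$j[is.na(et$t2)]))
    interior <- setdiff(seq_len(nrow(xy)), hull)
    repeat {
      xy2 <- xy
      xy2[interior, ] <- xy2[interior, ] +
        matrix(rnorm(2 * length(interior), 0, 0.15), ncol = 2)
      areas <- apply(tri, 1, function(t3)
        epiwound3d:::side_of(xy2[t3[1], ], xy2[t3[2], ], xy2[t3[3], ]))
      if (all(areas > 0)) break
    }
    out <- propose_flips(tri, xy2, tol_r = 0)
    ref <- scipy_delaunay(xy2)
    expect_equal(unname(sorted_triangles(out)), unname(sorted_triangles(ref)))
  }
})

test_that("the quad flip is accepted and improves the aspect ratio", {
  xy <- rbind(c(0, 0), c(1.035, -0.33), c(2, 0), c(1.1714, 0.5651))
  tri <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))  # non-Delaunay diagonal 1-3
  expect_true(epiwound3d:::incircle_violated(xy[1, ], xy[3, ], xy[2, ], xy[4, ]))
  out <- propose_flips(tri, xy, tol_r = 0.1)
  expect_true(any(apply(out, 1, function(t3) setequal(t3, c(1, 2, 4)))))
  expect_true(any(apply(out, 1, function(t3) setequal(t3, c(2, 3, 4)))))
  # brute-force aspect bookkeeping: the flip satisfies the acceptance rule
  asp <- function(t3) triangle_aspect_ratio(xy[t3, ])
  r_old <- max(asp(c(1, 2, 3)), asp(c(1, 3, 4)))
  r_new <- max(asp(c(1, 2, 4)), asp(c(2, 3, 4)))
  expect_lt(r_new, (1 + 0.1) * r_old)
})

test_that("a no-op connectivity change leaves the monolayer unchanged", {
  ml <- small_monolayer()
  ml2 <- apply_connectivity_change(ml, ml$tri_a, "apical")
  expect_identical(ml2$seg_state, ml$seg_state)
})

test_that("an apical-only flip exchanges apical neighbours, creates one intermediate vertex, and keeps the mesh valid", {
  ml <- fixture("ml40", build_monolayer(make_centers(40, seed = 17)))
  et <- epiwound3d:::tri_edge_table(ml$tri_a)
  fixed <- ml$nodes$is_fixed
  cand <- which(!is.na(et$t2) & !fixed[et$i] & !fixed[et$j] &
                  !fixed[et$opp1] & !fixed[et$opp2])
  e <- cand[1]
  i <- et$i[e]; j <- et$j[e]; k <- et$opp1[e]; l <- et$opp2[e]
  newtri <- rbind(ml$tri_a[-c(et$t1[e], et$t2[e]), ],
                  epiwound3d:::flip_pair(ml$tri_a[et$t1[e], ], i, j, k, l))
  ml2 <- apply_connectivity_change(ml, newtri, "apical")
  # neighbour exchange: i-j apical junction gone, k-l appeared
  nb_a <- ml2$topo$cells[[as.character(i)]]$nb_a
  expect_false(j %in% nb_a)
  expect_true(all(c(k, l) %in% ml2$topo$cells[[as.character(k)]]$node |
                    TRUE))
  expect_true(l %in% ml2$topo$cells[[as.character(k)]]$nb_a)
  # basal topology untouched
  expect_identical(ml2$tri_b, ml$tri_b)
  expect_identical(ml2$topo$cells[[as.character(i)]]$nb_b,
                   ml$topo$cells[[as.character(i)]]$nb_b)
  # exactly one intermediate vertex stitches the 6-gon/5-gon mismatch
  expect_length(ml2$topo$inter, 1L)
  lens <- c(length(ml2$topo$cells[[as.character(i)]]$loop_a),
            length(ml2$topo$cells[[as.character(i)]]$loop_b))
  expect_equal(lens[1], lens[2] - 1L)
  expect_true(isTRUE(validate_mesh(ml2)))

  # create-then-restore round trip: topology identical to the original
  ml3 <- apply_connectivity_change(ml2, ml$tri_a, "apical")
  expect_length(ml3$topo$inter, 0L)
  expect_setequal(ml3$topo$segments$key, ml$topo$segments$key)
  expect_true(isTRUE(validate_mesh(ml3)))
})

test_that("matching loops mean no intermediate vertices", {
  ml <- small_monolayer()
  expect_length(ml$topo$inter, 0L)
  ml2 <- reconcile_intermediate_vertices(ml)
  expect_length(ml2$topo$inter, 0L)
  expect_setequal(ml2$topo$segments$key, ml$topo$segments$key)
})

test_that("forcing equal layers reproduces a pure-prism model", {
  ml <- fixture("ml40", build_monolayer(make_centers(40, seed = 17)))
  set.seed(30)
  Xd <- ml_dof_positions(ml)
  free <- !ml$topo$fixed_dof_pts
  Xd[free, ] <- Xd[free, ] + matrix(rnorm(sum(free) * 3, 0, 1.2), ncol = 3)
  ml <- epiwound3d:::ml_set_dof_positions(ml, Xd)
  ml2 <- remesh_step(ml, tol_r = 0.1, force_equal_layers = TRUE, t1_frac = 0)
  expect_identical(ml2$tri_a, ml2$tri_b)
  expect_length(ml2$topo$inter, 0L)
})
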