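test_that("zero-noise 7-cell patch is a perfect hexagonal rosette", {
  cen <- rosette_centers(spacing = 12)
  expect_equal(nrow(cen), 7L)
  xy <- as.matrix(cen[, c("x_um", "y_um")])
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  nn <- unname(apply(d, 1, min))
  expect_equal(nn, rep(12, 7), tolerance = 1e-12)
  # one center in the middle, six around it
  d2 <- rowSums(sweep(xy, 2, colMeans(xy))^2)
  expect_equal(sum(d2 < 1e-9), 1L)
})

test_that("generation is deterministic in the seed and counts are exact", {
  a <- make_centers(60, seed = 5)
  b <- make_centers(60, seed = 5)
  c_ <- make_centers(60, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$x_um, c_$x_um)))
  expect_equal(nrow(make_centers(205, seed = 2)), 205L)
})

test_that("infeasible patch sizing is an explicit error", {
  spec <- patch_spec(100, spacing = 12, patch_side = 30)
  expect_error(generate_hex_patch(spec), "sizing")
  expect_error(patch_spec(50, noise_amplitude = 0.5), "noise_amplitude")
})

test_that("a 205-cell jittered patch triangulates without slivers", {
  cen <- generate_hex_patch(patch_spec(205, noise_amplitude = 0.2, seed = 9))
  xy <- as.matrix(cen[, c("x_um", "y_um")])
  tri <- delaunay_triangulate(xy)
  # brute-force aspect scan over every triangle
  r <- apply(tri, 1, function(t3) triangle_aspect_ratio(xy[t3, ]))
  expect_lt(max(r), 5)
})

test_that("ablation regions are central, connected, and respect the boundary", {
  cen <- make_centers(205, seed = 4)
  xy <- as.matrix(cen[, c("x_um", "y_um")])
  one <- select_ablation_region(cen, 1)
  d2 <- rowSums(sweep(xy, 2, colMeans(xy))^2)
  expect_equal(one, cen$cell_id[which.min(d2)])

  eight <- select_ablation_region(cen, 8)
  expect_length(eight, 8L)
  # breadth-first-search connectivity oracle over the Delaunay adjacency
  tri <- delaunay_triangulate(xy)
  adj <- epiwound3d:::delaunay_adjacency(tri, nrow(xy))
  seen <- eight[1]; frontier <- eight[1]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier])), eight), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_setequal(seen, eight)

  expect_error(select_ablation_region(cen, 100000), "interior")
})

test_that("zero-noise interior cells have equal areas after building", {
  cen <- generate_hex_patch(patch_spec(37, spacing = 12, noise_amplitude = 0))
  ml <- build_monolayer(cen)
  interior <- which(!ml$nodes$is_fixed[sapply(ml$topo$cells, `[[`, "node")])
  areas <- sapply(interior, function(k) epiwound3d:::apical_cell_area(ml, k))
  expect_lt(diff(range(areas)) / mean(areas), 1e-9)
})

test_that("center tables round-trip through the CSV contract", {
  cen <- make_centers(30, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_centers(cen, p)
  expect_equal(as.data.frame(read_centers(p)), as.data.frame(cen),
               tolerance = 1e-12)
})
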