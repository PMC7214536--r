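test_that("the contractility schedule follows the activation and decay law", {
  prot <- wound_protocol(1L, Y_Ac = 2.3, Y_Lc = 0.8)
  expect_equal(contractility_schedule(0, prot), c(0, 0))
  expect_equal(contractility_schedule(6, prot), c(0, 0))
  expect_equal(contractility_schedule(46, prot), c(2.3 * (1 - 40 / 400), 0.8))
  expect_equal(contractility_schedule(46, prot)[1], 2.07)
  # limit t -> t_w+ approaches the full amplitude
  expect_equal(contractility_schedule(6 + 1e-9, prot)[1], 2.3, tolerance = 1e-6)
  # clamp at zero far beyond the decay span
  expect_equal(contractility_schedule(6 + 500, prot)[1], 0)
})

test_that("ablating an empty set is the identity", {
  ml <- small_monolayer()
  prot <- wound_protocol(integer(0))
  expect_identical(ablate(ml, prot), ml)
})

test_that("ablation degrades exactly the segments owned only by ablated cells", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  abl <- std$ablated
  s <- ml$topo$segments
  # brute-force owner scan from the segment keys, by segment family:
  # nodal in-layer/diagonal own the two cells, nodal vertical its one cell,
  # in-layer junctions the two cells sharing the dual edge, tricellular
  # verticals all three cells
  owners <- function(key) {
    if (grepl("^n[ABD]:", key)) {
      as.integer(strsplit(sub("^n[ABD]:", "", key), "-")[[1]])
    } else if (grepl("^nV:", key)) {
      as.integer(sub("^nV:", "", key))
    } else if (grepl("^v[AB]:", key)) {
      tr <- strsplit(strsplit(sub("^v[AB]:", "", key), "|", fixed = TRUE)[[1]], "-")
      intersect(as.integer(tr[[1]]), as.integer(tr[[2]]))
    } else if (grepl("^vV:", key)) {
      as.integer(strsplit(sub("^vV:", "", key), "-")[[1]])
    } else {
      NULL  # intermediate bridges and face diagonals: checked elsewhere
    }
  }
  set.seed(1)
  checked <- 0
  for (k in sample(nrow(s), nrow(s))) {
    own <- owners(s$key[k])
    if (is.null(own)) next
    expected <- if (all(ml$nodes$state[own] == "ablated")) 0.01 else 1
    expect_equal(s$scale[k], expected)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
  # volume penalty removed from ablated cells only
  expect_false(any(ml$nodes$volume_penalty_on[abl]))
  expect_error(ablate(small_monolayer(), wound_protocol(1L)), "boundary")
})

test_that("the apical wound perimeter tiles the ablated polygons", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  Xp <- ml_points(ml)
  kabl <- which(sapply(ml$topo$cells, function(cl)
    ml$nodes$state[cl$node] == "ablated"))
  polysum <- sum(sapply(kabl, function(k)
    epiwound3d:::apical_cell_area(ml, k, Xp))) * ml$scale^2
  expect_equal(apical_wound_area(ml, check_simple = TRUE), polysum,
               tolerance = 1e-9)
})

test_that("wound-edge vertices are relaxed degrees of freedom", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  v <- ml$topo$verts
  abl <- std$ablated
  for (k in which(v$layer == "a")) {
    tr <- ml$tri_a[v$tri_row[k], ]
    n_abl <- sum(ml$nodes$state[tr] == "ablated")
    if (n_abl %in% 1:2) expect_equal(v$kind[k], "relaxed")
  }
})

test_that("recoil expands the apical wound before the purse string activates", {
  std <- std_patch()
  sim <- fixture("recoil_sim", {
    prot <- wound_protocol(std$ablated, Y_Ac = 2.3)
    run_simulation(std$centers, material_params(), prot, solver_settings(),
                   t_end = 6)
  })
  ts <- tidy(sim)
  expect_gt(ts$wound_area_um2[nrow(ts)], ts$wound_area_um2[1])
})

test_that("wound maintenance is the identity when nothing is below threshold and the closure flag latches", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  prot <- wound_protocol(std$ablated)
  ml$time <- 0  # before t_w: no removal can fire
  ml2 <- maintain_wound(ml, prot)
  expect_identical(ml2$nodes$state, ml$nodes$state)
  ml2$wound$closed <- TRUE
  ml3 <- maintain_wound(ml2, prot)
  expect_true(ml3$wound$closed)
})

test_that("wound-edge counts match a brute-force incidence scan", {
  std <- std_patch()
  ml <- fixture("wounded80", {
    m <- build_monolayer(std$centers, height = 35, length_scale = 35)
    ablate(m, wound_protocol(std$ablated))
  })
  wc <- wound_edge_counts(ml)
  pv <- unique(unlist(ml$topo$perimeter$cycles))
  n_edge <- sum(sapply(ml$topo$cells, function(cl)
    ml$nodes$state[cl$node] == "alive" && any(cl$loop_a %in% pv)))
  expect_equal(unname(wc[1]), n_edge)
  expect_gte(wc[2], length(pv))
  expect_true(all(wc >= 0))
})
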