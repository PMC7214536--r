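#' Build a two-layer prism-cell monolayer from cell centers
#'
#' Constructs the hybrid cell-center/vertex representation: apical and basal
#' cell-center nodes (initially sharing x,y and separated by `height` in z), a
#' Delaunay triangulation per layer (initially identical), one boundary-vertex
#' per triangle per layer located at the triangle barycenter, and the two
#' coupled bar networks (nodal and vertex) including vertical and diagonal
#' lateral segments. A ring of boundary nodes, placed one lattice spacing
#' outward of the patch outline, closes the polygons of rim cells; ring
#' nodes carry no cell and are fixed, as are the rim cells themselves.
#' All rest lengths are initialized to current lengths and each cell's
#' reference volume V0 to its current volume.
#'
#' The model's mechanics is formulated in dimensionless lengths: coordinates
#' are divided by `length_scale` on input (the calibrated material parameters
#' presume lengths of order the monolayer height, so [run_simulation()] uses
#' `length_scale = height`); geometric metrics convert back to micrometers.
#'
#' @param centers tibble/data.frame with columns `cell_id`, `x_um`, `y_um`.
#' @param height initial monolayer height (um), apical plane at z = height.
#' @param length_scale normalization length (um) applied to all coordinates;
#'   1 keeps micrometers.
#' @return an object of class `monolayer`.
#' @export
build_monolayer <- function(centers, height = 35, length_scale = 1) {
  xy <- as.matrix(centers[, c("x_um", "y_um")]) / length_scale
  height <- height / length_scale
  n <- nrow(xy)
  if (n < 7L) stop("need at least 7 non-collinear cell centers")
  ring <- mirror_boundary_ring(xy)
  all_xy <- rbind(xy, ring)
  nn <- nrow(all_xy)
  tri <- delaunay_triangulate(all_xy)

  is_cell <- c(rep(TRUE, n), rep(FALSE, nn - n))
  # rim cells: adjacent to a ring node
  adj <- delaunay_adjacency(tri, nn)
  rim <- vapply(seq_len(n), function(i) any(adj[[i]] > n), logical(1L))
  nodes <- tibble::tibble(
    node = seq_len(nn),
    is_cell = is_cell,
    is_ring = !is_cell,
    is_fixed = !is_cell | c(rim, rep(TRUE, nn - n)),
    state = ifelse(is_cell, "alive", "ring"),
    volume_penalty_on = is_cell,
    V0 = NA_real_,
    A0 = NA_real_)

  ml <- structure(list(
    nodes = nodes,
    xa = cbind(all_xy, height),
    xb = cbind(all_xy, 0),
    tri_a = tri,
    tri_b = tri,
    free_verts = tibble::tibble(key = character(), x = double(), y = double(), z = double()),
    relaxed_keys = character(),
    seg_state = tibble::tibble(key = character(), L = double(), L0 = double()),
    height = height,
    scale = length_scale,
    time = 0,
    wound = list(active = FALSE, max_area = NA_real_, closed = FALSE,
                 closure_time = NA_real_, init_mean_area = NA_real_),
    topo = NULL, cache = NULL), class = "monolayer")
  colnames(ml$xa) <- colnames(ml$xb) <- c("x", "y", "z")
  ml <- rebuild_topology(ml)
  # stress-free initialization: L = L0 = current length, V0 = current volume
  len <- segment_lengths(ml)
  ml$seg_state <- tibble::tibble(key = ml$topo$segments$key, L = len, L0 = len)
  ml$topo$segments$L <- len
  ml$topo$segments$L0 <- len
  vols <- cell_volumes(ml)
  ml$nodes$V0[match(names(vols), as.character(ml$nodes$node))] <- vols
  areas0 <- vapply(seq_along(ml$topo$cells), function(k)
    apical_cell_area(ml, k), numeric(1L))
  ml$nodes$A0[vapply(ml$topo$cells, function(cl) cl$node, integer(1L))] <- areas0
  ml$wound$init_mean_area <- mean(areas0)
  sel <- ml$topo$segments$network == "vertex" &
    ml$topo$segments$orientation %in% c("apical", "basal")
  ml$wound$init_junction_len <- mean(ml$topo$segments$L0[sel])
  ml
}

# Boundary-node ring enclosing the patch (no cell is attached to these
# nodes): every cell on the convex hull of the current point set is pushed
# one lattice spacing outward, iterating until no cell remains on the hull,
# and large angular gaps are densified. This closes the vertex polygon of
# every rim cell regardless of the patch outline.
mirror_boundary_ring <- function(xy) {
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  s <- mean(apply(d, 1L, min))  # spacing estimate: mean nearest-neighbour gap
  ctr <- colMeans(xy)
  ring <- NULL
  for (pass in 1:5) {
    all_pts <- rbind(xy, ring)
    tri <- delaunay_triangulate(all_pts)
    et <- tri_edge_table(tri)
    hull <- sort(unique(c(et$i[is.na(et$t2)], et$j[is.na(et$t2)])))
    hull_cells <- hull[hull <= n]
    if (!length(hull_cells)) break
    u <- sweep(xy[hull_cells, , drop = FALSE], 2L, ctr)
    u <- u / sqrt(rowSums(u^2))
    ring <- rbind(ring, xy[hull_cells, , drop = FALSE] + s * u)
  }
  if (is.null(ring)) stop("boundary ring construction failed")
  # densify angular gaps wider than ~1.3 spacings
  ang <- atan2(ring[, 2L] - ctr[2L], ring[, 1L] - ctr[1L])
  ord <- order(ang)
  ring <- ring[ord, , drop = FALSE]
  extra <- NULL
  m <- nrow(ring)
  for (k in seq_len(m)) {
    a <- ring[k, ]; b <- ring[if (k == m) 1L else k + 1L, ]
    gap <- sqrt(sum((a - b)^2))
    if (gap > 1.3 * s) {
      mid <- (a + b) / 2
      v <- mid - ctr
      extra <- rbind(extra, ctr + v / sqrt(sum(v^2)) * (sqrt(sum((a - ctr)^2)) + sqrt(sum((b - ctr)^2))) / 2)
    }
  }
  ring <- rbind(ring, extra)
  # deduplicate near-coincident points
  keep <- rep(TRUE, nrow(ring))
  for (i in seq_len(nrow(ring))) {
    if (!keep[i] || i == nrow(ring)) next
    later <- (i + 1L):nrow(ring)
    d2 <- (ring[later, 1L] - ring[i, 1L])^2 + (ring[later, 2L] - ring[i, 2L])^2
    keep[later][d2 < (0.3 * s)^2] <- FALSE
  }
  ring[keep, , drop = FALSE]
}

#' Longest-to-shortest edge aspect ratio of a triangle
#'
#' Dimensionless quality measure >= 1, equal to 1 iff the triangle is
#' equilateral; returns `Inf` for a zero-length edge.
#'
#' @param p 3 x d numeric matrix of triangle corner coordinates (d = 2 or 3).
#' @return scalar aspect ratio.
#' @export
triangle_aspect_ratio <- function(p) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == 3L)
  e <- sqrt(c(sum((p[1L, ] - p[2L, ])^2),
              sum((p[2L, ] - p[3L, ])^2),
              sum((p[3L, ] - p[1L, ])^2)))
  if (min(e) <= 0) return(Inf)
  max(e) / min(e)
}

# ---- topology rebuild -------------------------------------------------------

# Star of a node: its incident triangles in consistent cyclic (CCW) order,
# walked combinatorially through shared edges. Returns triangle row indices.
star_walk <- function(node, tri, edge_lookup) {
  rows <- which(tri[, 1L] == node | tri[, 2L] == node | tri[, 3L] == node)
  if (length(rows) < 3L) stop("open star: node ", node, " is not an interior cell")
  # orient each triangle as (node, u, w) preserving stored (CCW) cyclic order
  uw <- t(vapply(rows, function(r) {
    t3 <- tri[r, ]
    i <- which(t3 == node)
    t3[((i - 1L + 1L:2L) %% 3L) + 1L]
  }, integer(2L)))
  ord <- integer(length(rows))
  ord[1L] <- 1L
  used <- logical(length(rows)); used[1L] <- TRUE
  for (k in seq_len(length(rows) - 1L)) {
    w <- uw[ord[k], 2L]
    nxt <- which(!used & uw[, 1L] == w)
    if (length(nxt) != 1L) stop("broken star walk around node ", node)
    ord[k + 1L] <- nxt
    used[nxt] <- TRUE
  }
  if (uw[ord[length(rows)], 2L] != uw[ord[1L], 1L]) {
    stop("star walk around node ", node, " does not close")
  }
  rows[ord]
}

# Detect intermediate vertices from apical/basal edge-set disagreement.
# Each single-layer-only junction must sit in a clean flipped quad; otherwise
# the caller (remesh) forces a synchronising flip first.
detect_intermediates <- function(tri_a, tri_b) {
  et_a <- tri_edge_table(tri_a)
  et_b <- tri_edge_table(tri_b)
  key_a <- paste(et_a$i, et_a$j)
  key_b <- paste(et_b$i, et_b$j)
  only_a <- et_a[!(key_a %in% key_b), , drop = FALSE]
  only_b <- et_b[!(key_b %in% key_a), , drop = FALSE]
  res <- list()
  resolve <- function(e, et_other, flavour) {
    # edge {i,j} exists only in this layer with opposite vertices opp1/opp2;
    # the other layer must contain edge {opp1,opp2} with opposites {i,j}
    if (is.na(e$opp2)) return(NULL)  # hull edge: ignore
    oi <- min(e$opp1, e$opp2); oj <- max(e$opp1, e$opp2)
    m <- which(et_other$i == oi & et_other$j == oj)
    if (length(m) != 1L) return(NA)
    other <- et_other[m, ]
    if (is.na(other$opp2)) return(NA)
    if (!setequal(c(other$opp1, other$opp2), c(e$i, e$j))) return(NA)
    quad <- sort(c(e$i, e$j, oi, oj))
    list(key = paste0("m:", paste(quad, collapse = "-"), ":", e$i, "-", e$j, ":", flavour),
         quad = quad,
         # pair adjacent only in this layer, pair adjacent only in the other
         this_pair = c(e$i, e$j), other_pair = c(oi, oj),
         # triples present only in this layer / only in the other layer
         this_triples = rbind(sort(c(e$i, e$j, e$opp1)), sort(c(e$i, e$j, e$opp2))),
         other_triples = rbind(sort(c(oi, oj, other$opp1)), sort(c(oi, oj, other$opp2))),
         flavour = flavour)
  }
  bad <- list()
  for (k in seq_len(nrow(only_a))) {
    r <- resolve(only_a[k, ], et_b, "a")
    if (is.null(r)) next
    if (!is.list(r)) { bad[[length(bad) + 1L]] <- c(only_a$i[k], only_a$j[k], 1L); next }
    res[[r$key]] <- r
  }
  for (k in seq_len(nrow(only_b))) {
    r <- resolve(only_b[k, ], et_a, "b")
    if (is.null(r)) next
    if (!is.list(r)) { bad[[length(bad) + 1L]] <- c(only_b$i[k], only_b$j[k], 2L); next }
    res[[r$key]] <- r
  }
  # the apical-only and basal-only views of the same quad are one vertex:
  # canonical identity = quad + the pair that is apical-adjacent
  canon <- list()
  for (r in res) {
    apair <- if (r$flavour == "a") r$this_pair else r$other_pair
    key <- paste0("m:", paste(r$quad, collapse = "-"), ":", paste(sort(apair), collapse = "-"))
    ap_triples <- if (r$flavour == "a") r$this_triples else r$other_triples
    bs_triples <- if (r$flavour == "a") r$other_triples else r$this_triples
    canon[[key]] <- list(key = key, quad = r$quad,
                         apical_triples = ap_triples, basal_triples = bs_triples)
  }
  list(intermediates = canon,
       unresolved = if (length(bad)) do.call(rbind, bad) else NULL)
}

#' Rebuild the derived topology of a monolayer
#'
#' Recomputes vertices, intermediate vertices, cell loops, lateral faces,
#' segments and the volume tetrahedralization from the two layer
#' triangulations and persistent per-entity state (free-vertex positions,
#' relaxed-vertex keys, segment rest lengths). Called after any connectivity
#' change; persistent segments keep their rest lengths, new ones are born
#' stress-free.
#'
#' @param ml a `monolayer`.
#' @return the monolayer with a fresh `$topo` (and cleared assembly cache).
#' @export
rebuild_topology <- function(ml) {
  act <- which(ml$nodes$state != "removed")
  n_act <- length(act)
  node_row <- integer(nrow(ml$nodes)); node_row[act] <- seq_len(n_act)
  tri_a <- ml$tri_a; tri_b <- ml$tri_b

  det_int <- detect_intermediates(tri_a, tri_b)
  if (!is.null(det_int$unresolved)) {
    stop("unresolvable apical/basal connectivity mismatch at edges: ",
         paste(apply(det_int$unresolved, 1L, function(r) paste(r[1L], r[2L], sep = "-")),
               collapse = ", "))
  }
  inter <- det_int$intermediates

  key_a <- paste0("a:", triangle_keys(tri_a))
  key_b <- paste0("b:", triangle_keys(tri_b))

  # ---- point bookkeeping ----
  # dof points: [apical nodes][basal nodes][free vertices (relaxed + intermediate)]
  relaxed_a <- key_a %in% ml$relaxed_keys
  relaxed_b <- key_b %in% ml$relaxed_keys
  free_keys <- c(key_a[relaxed_a], key_b[relaxed_b], names(inter))
  n_free <- length(free_keys)
  n_dof <- 2L * n_act + n_free
  free_row <- stats::setNames(2L * n_act + seq_len(n_free), free_keys)

  vert_a <- tibble::tibble(layer = "a", key = key_a, tri_row = seq_len(nrow(tri_a)),
                           kind = ifelse(relaxed_a, "relaxed", "constrained"))
  vert_b <- tibble::tibble(layer = "b", key = key_b, tri_row = seq_len(nrow(tri_b)),
                           kind = ifelse(relaxed_b, "relaxed", "constrained"))
  verts <- rbind(vert_a, vert_b)
  # constrained vertices are derived points appended after the dofs
  con <- which(verts$kind == "constrained")
  verts$point <- NA_integer_
  verts$point[con] <- n_dof + seq_along(con)
  rel <- which(verts$kind == "relaxed")
  verts$point[rel] <- free_row[verts$key[rel]]
  n_con <- length(con)

  cells_nodes <- which(ml$nodes$is_cell & ml$nodes$state != "removed")
  n_cells <- length(cells_nodes)
  mid_point <- n_dof + n_con + seq_len(n_cells)  # cell midpoints, derived
  n_pts <- n_dof + n_con + n_cells

  # S: points = S %*% dofs (scalar weights, applied per coordinate)
  si <- c(seq_len(n_dof))
  sj <- c(seq_len(n_dof))
  sx <- rep(1, n_dof)
  if (n_con > 0L) {
    cv <- verts[con, ]
    par <- t(vapply(seq_len(nrow(cv)), function(k) {
      tr <- if (cv$layer[k] == "a") tri_a[cv$tri_row[k], ] else tri_b[cv$tri_row[k], ]
      node_row[tr]
    }, integer(3L)))
    off <- ifelse(cv$layer == "a", 0L, n_act)
    si <- c(si, rep(cv$point, each = 3L))
    sj <- c(sj, as.integer(t(par)) + rep(off, each = 3L))
    sx <- c(sx, rep(1 / 3, 3L * nrow(cv)))
  }
  si <- c(si, rep(mid_point, each = 2L))
  sj <- c(sj, as.integer(rbind(node_row[cells_nodes], node_row[cells_nodes] + n_act)))
  sx <- c(sx, rep(0.5, 2L * n_cells))
  S <- Matrix::sparseMatrix(i = si, j = sj, x = sx, dims = c(n_pts, n_dof))

  # stable identity string per point row (node / vertex key / midpoint),
  # used for persistent segment keys and deterministic fan anchors
  pt_id <- character(n_pts)
  pt_id[seq_len(n_act)] <- paste0("na:", act)
  pt_id[n_act + seq_len(n_act)] <- paste0("nb:", act)
  pt_id[verts$point] <- verts$key
  if (length(free_row)) pt_id[free_row] <- names(free_row)
  pt_id[mid_point] <- paste0("mid:", cells_nodes)

  vmap_a <- stats::setNames(verts$point[verts$layer == "a"], verts$key[verts$layer == "a"])
  vmap_b <- stats::setNames(verts$point[verts$layer == "b"], verts$key[verts$layer == "b"])
  tri_row_pt_a <- verts$point[verts$layer == "a"][order(verts$tri_row[verts$layer == "a"])]
  tri_row_pt_b <- verts$point[verts$layer == "b"][order(verts$tri_row[verts$layer == "b"])]

  # triple -> intermediate key lookups
  m_by_triple_a <- character(0)
  m_by_triple_b <- character(0)
  for (m in inter) {
    ta <- apply(m$apical_triples, 1L, paste, collapse = "-")
    tb <- apply(m$basal_triples, 1L, paste, collapse = "-")
    m_by_triple_a[ta] <- m$key
    m_by_triple_b[tb] <- m$key
  }

  # ---- cell loops ----
  cells <- vector("list", n_cells)
  fixed_node <- ml$nodes$is_fixed
  for (k in seq_len(n_cells)) {
    nd <- cells_nodes[k]
    sa <- star_walk(nd, tri_a, NULL)
    sb <- star_walk(nd, tri_b, NULL)
    loop_a <- tri_row_pt_a[sa]
    loop_b <- tri_row_pt_b[sb]
    # neighbour sequence: third node of the edge between consecutive star
    # triangles equals the shared junction partner
    nb_a <- vapply(seq_along(sa), function(i) {
      t1 <- tri_a[sa[i], ]; t2 <- tri_a[sa[if (i == length(sa)) 1L else i + 1L], ]
      setdiff(intersect(t1, t2), nd)
    }, integer(1L))
    nb_b <- vapply(seq_along(sb), function(i) {
      t1 <- tri_b[sb[i], ]; t2 <- tri_b[sb[if (i == length(sb)) 1L else i + 1L], ]
      setdiff(intersect(t1, t2), nd)
    }, integer(1L))
    cells[[k]] <- list(node = nd, row = k,
                       loop_a = loop_a, loop_b = loop_b,
                       key_a = key_a[sa], key_b = key_b[sb],
                       nb_a = nb_a, nb_b = nb_b,
                       mid = mid_point[k],
                       state = ml$nodes$state[nd],
                       volume_penalty_on = ml$nodes$volume_penalty_on[nd],
                       V0 = ml$nodes$V0[nd])
  }
  names(cells) <- as.character(cells_nodes)

  # ---- lateral faces (per junction between two nodes, >=1 of them a cell) ----
  faces <- build_faces(ml, cells, inter, vmap_a, vmap_b, free_row,
                       m_by_triple_a, m_by_triple_b)

  # ---- segments ----
  segs <- build_segments(ml, cells, faces, inter, tri_a, tri_b,
                         node_row, n_act, vmap_a, vmap_b, free_row, fixed_node,
                         pt_id)

  # ---- volume tetrahedra ----
  tets <- build_tets(cells, faces, node_row, n_act, pt_id)

  topo <- list(act = act, node_row = node_row, n_act = n_act, n_dof = n_dof,
               n_pts = n_pts, S = S, verts = verts, free_keys = free_keys,
               pt_id = pt_id,
               free_row = free_row, inter = inter,
               cells = cells, faces = faces, segments = segs,
               tets = tets$tets, tet_cell = tets$tet_cell,
               vmap_a = vmap_a, vmap_b = vmap_b,
               fixed_dof_pts = c(fixed_node[act], fixed_node[act], rep(FALSE, n_free)))
  ml$topo <- topo
  ml$cache <- NULL
  # free-vertex store: drop stale entries, add new ones at their natural birth
  # positions (barycenter for relaxed, mid-height bridge average for
  # intermediates) -- needs point positions, so do it via ml_dof_positions
  ml <- sync_free_vertices(ml)
  # join persistent rest lengths; new segments born stress-free
  len <- segment_lengths(ml)
  idx <- match(ml$topo$segments$key, ml$seg_state$key)
  L <- ifelse(is.na(idx), NA_real_, ml$seg_state$L[idx])
  L0 <- ifelse(is.na(idx), NA_real_, ml$seg_state$L0[idx])
  newb <- is.na(idx)
  if (any(newb)) {
    # vertical merge rule: an intermediate vertex disappearing leaves a full
    # tricellular line whose rest length is the sum of its two halves
    nk <- ml$topo$segments$key[newb]
    mk_a <- sub("^vV:", "vVm:", nk)
    la <- ml$seg_state$L[match(paste0(mk_a, ":a"), ml$seg_state$key)] +
      ml$seg_state$L[match(paste0(mk_a, ":b"), ml$seg_state$key)]
    l0a <- ml$seg_state$L0[match(paste0(mk_a, ":a"), ml$seg_state$key)] +
      ml$seg_state$L0[match(paste0(mk_a, ":b"), ml$seg_state$key)]
    merged <- startsWith(nk, "vV:") & !is.na(la)
    L[newb][merged] <- la[merged]
    L0[newb][merged] <- l0a[merged]
  }
  still <- is.na(L)
  L[still] <- len[still]
  L0[still] <- len[still]
  ml$topo$segments$L <- L
  ml$topo$segments$L0 <- L0
  ml$seg_state <- tibble::tibble(key = ml$topo$segments$key, L = L, L0 = L0)
  if (ml$wound$active) ml <- refresh_wound_membership(ml)
  ml
}

# initialize positions of newly created free vertices and drop stale entries
sync_free_vertices <- function(ml) {
  topo <- ml$topo
  keys <- topo$free_keys
  old <- ml$free_verts
  pos <- matrix(NA_real_, length(keys), 3L)
  hit <- match(keys, old$key)
  if (any(!is.na(hit))) {
    pos[!is.na(hit), ] <- as.matrix(old[hit[!is.na(hit)], c("x", "y", "z")])
  }
  miss <- which(is.na(hit))
  if (length(miss)) {
    # need derived positions of constrained vertices: compute with current
    # free positions zeroed (missing free rows don't feed constrained rows)
    Xd <- rbind(ml$xa[topo$act, , drop = FALSE], ml$xb[topo$act, , drop = FALSE],
                matrix(0, length(keys), 3L))
    filled <- !is.na(hit)
    Xd[2L * topo$n_act + which(filled), ] <- pos[filled, ]
    Xp <- as.matrix(topo$S %*% Xd)
    for (k in miss) {
      key <- keys[k]
      if (startsWith(key, "m:")) {
        m <- topo$inter[[key]]
        vp <- c(vapply(seq_len(2L), function(r)
          topo$vmap_a[[paste0("a:", paste(m$apical_triples[r, ], collapse = "-"))]], integer(1L)),
          vapply(seq_len(2L), function(r)
            topo$vmap_b[[paste0("b:", paste(m$basal_triples[r, ], collapse = "-"))]], integer(1L)))
        pos[k, ] <- colMeans(Xp[vp, , drop = FALSE])
      } else {
        # relaxed vertex born at its barycentric (interpolated) position
        lay <- substr(key, 1L, 1L)
        tr <- as.integer(strsplit(substr(key, 3L, nchar(key)), "-")[[1L]])
        X <- if (lay == "a") ml$xa else ml$xb
        pos[k, ] <- colMeans(X[tr, , drop = FALSE])
      }
      Xd[2L * topo$n_act + k, ] <- pos[k, ]
      Xp <- as.matrix(topo$S %*% Xd)  # refresh in case intermediates chain
    }
  }
  ml$free_verts <- tibble::tibble(key = keys, x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  ml
}

# ---- faces -----------------------------------------------------------------

# A lateral face per junction pair {i,j}: apical corner points (0 or 2), basal
# corner points (0 or 2), and the side chains (possibly through an
# intermediate vertex). Stored orientation-free; cells traverse it according
# to their own loop direction.
build_faces <- function(ml, cells, inter, vmap_a, vmap_b, free_row,
                        m_by_triple_a, m_by_triple_b) {
  et_a <- tri_edge_table(ml$tri_a)
  et_b <- tri_edge_table(ml$tri_b)
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ka <- pair_key(et_a$i, et_a$j)
  kb <- pair_key(et_b$i, et_b$j)
  keys <- union(ka[!is.na(et_a$t2)], kb[!is.na(et_b$t2)])
  is_cell <- ml$nodes$is_cell & ml$nodes$state != "removed"
  faces <- list()
  for (key in keys) {
    ij <- as.integer(strsplit(key, " ")[[1L]])
    if (!any(is_cell[ij])) next
    a_idx <- match(key, ka)
    b_idx <- match(key, kb)
    ap <- NULL; bs <- NULL
    if (!is.na(a_idx) && !is.na(et_a$t2[a_idx])) {
      tr1 <- sort(c(ij, et_a$opp1[a_idx])); tr2 <- sort(c(ij, et_a$opp2[a_idx]))
      ap <- list(triples = rbind(tr1, tr2),
                 pts = c(vmap_a[[paste0("a:", paste(tr1, collapse = "-"))]],
                         vmap_a[[paste0("a:", paste(tr2, collapse = "-"))]]))
    }
    if (!is.na(b_idx) && !is.na(et_b$t2[b_idx])) {
      tr1 <- sort(c(ij, et_b$opp1[b_idx])); tr2 <- sort(c(ij, et_b$opp2[b_idx]))
      bs <- list(triples = rbind(tr1, tr2),
                 pts = c(vmap_b[[paste0("b:", paste(tr1, collapse = "-"))]],
                         vmap_b[[paste0("b:", paste(tr2, collapse = "-"))]]))
    }
    if (is.null(ap) && is.null(bs)) next
    # side chains: for each apical corner triple, direct partner or intermediate
    side <- function(tr) {
      tkey <- paste(tr, collapse = "-")
      if (!is.null(bs) && any(apply(bs$triples, 1L, function(x) all(x == tr)))) {
        w <- which(apply(bs$triples, 1L, function(x) all(x == tr)))
        list(kind = "direct", to = bs$pts[w])
      } else if (tkey %in% names(m_by_triple_a)) {
        list(kind = "mid", m = free_row[[m_by_triple_a[[tkey]]]],
             mkey = m_by_triple_a[[tkey]])
      } else {
        stop("face ", key, ": apical corner ", tkey, " has no basal partner or intermediate")
      }
    }
    chains <- NULL
    if (!is.null(ap)) {
      chains <- lapply(1:2, function(w) side(ap$triples[w, ]))
    }
    # for a mid chain, find which basal corner hangs off the same intermediate
    resolve_mid_basal <- function(mkey) {
      if (is.null(bs)) return(NA_integer_)
      for (w in 1:2) {
        tkey <- paste(bs$triples[w, ], collapse = "-")
        if (tkey %in% names(m_by_triple_b) && m_by_triple_b[[tkey]] == mkey) return(bs$pts[w])
      }
      NA_integer_
    }
    face <- list(i = ij[1L], j = ij[2L], key = key,
                 ap_pts = if (is.null(ap)) integer(0) else ap$pts,
                 ap_triples = if (is.null(ap)) NULL else ap$triples,
                 bs_pts = if (is.null(bs)) integer(0) else bs$pts,
                 bs_triples = if (is.null(bs)) NULL else bs$triples)
    if (!is.null(ap)) {
      face$side <- lapply(1:2, function(w) {
        ch <- chains[[w]]
        if (ch$kind == "direct") list(kind = "direct", down = ch$to)
        else list(kind = "mid", m = ch$m, down = resolve_mid_basal(ch$mkey))
      })
    } else {
      # basal-only face: both basal corners must share one intermediate
      mk <- vapply(1:2, function(w) {
        tkey <- paste(bs$triples[w, ], collapse = "-")
        if (tkey %in% names(m_by_triple_b)) m_by_triple_b[[tkey]] else NA_character_
      }, character(1L))
      if (anyNA(mk) || mk[1L] != mk[2L]) {
        stop("basal-only face ", key, " lacks a common intermediate vertex")
      }
      face$m <- free_row[[mk[1L]]]
    }
    faces[[key]] <- face
  }
  faces
}

# ordered cycle of point rows of a face, traversed for the cell whose apical
# (or basal) loop visits `from_pt` then `to_pt` on this junction
face_cycle <- function(face, from_pt, to_pt, layer) {
  if (layer == "a") {
    stopifnot(length(face$ap_pts) == 2L)
    w_from <- match(from_pt, face$ap_pts)
    w_to <- match(to_pt, face$ap_pts)
    s_to <- face$side[[w_to]]; s_from <- face$side[[w_from]]
    cyc <- c(from_pt, to_pt)
    if (s_to$kind == "mid") cyc <- c(cyc, s_to$m)
    if (!is.na(s_to$down) && length(s_to$down)) cyc <- c(cyc, s_to$down)
    if (!is.na(s_from$down) && length(s_from$down)) cyc <- c(cyc, s_from$down)
    if (s_from$kind == "mid") cyc <- c(cyc, s_from$m)
    unique(cyc)
  } else {
    # basal-only face: cycle = basal edge (in given order) then intermediate
    stopifnot(length(face$ap_pts) == 0L)
    c(from_pt, to_pt, face$m)
  }
}

# ---- segments --------------------------------------------------------------

build_segments <- function(ml, cells, faces, inter, tri_a, tri_b,
                           node_row, n_act, vmap_a, vmap_b, free_row, fixed_node,
                           pt_id) {
  et_a <- tri_edge_table(tri_a)
  et_b <- tri_edge_table(tri_b)
  segs <- list()
  add <- function(p1, p2, network, orientation, key, scale, gamma_on) {
    segs[[length(segs) + 1L]] <<- data.frame(
      p1 = p1, p2 = p2, network = network, orientation = orientation,
      key = key, scale = scale, gamma_on = gamma_on, stringsAsFactors = FALSE)
  }
  nstate <- ml$nodes$state
  abl <- function(nodes_) all(nstate[nodes_] == "ablated")
  seg_scale_nodes <- function(mat) {
    # rows of node ids owning the segment: 0.01 iff every owner is ablated;
    # interfaces shared with a live cell keep full stiffness
    ifelse(vapply(seq_len(nrow(mat)), function(k) abl(stats::na.omit(unlist(mat[k, ]))), logical(1L)), 0.01, 1)
  }

  # nodal in-layer (skip fixed-fixed)
  for (lay in c("a", "b")) {
    et <- if (lay == "a") et_a else et_b
    keep <- !(fixed_node[et$i] & fixed_node[et$j])
    e <- et[keep, , drop = FALSE]
    if (nrow(e)) {
      off <- if (lay == "a") 0L else n_act
      add(node_row[e$i] + off, node_row[e$j] + off, "nodal",
          if (lay == "a") "apical" else "basal",
          paste0("n", toupper(lay), ":", e$i, "-", e$j),
          seg_scale_nodes(cbind(e$i, e$j)), FALSE)
    }
  }
  # nodal vertical
  vn <- which(!fixed_node & ml$nodes$state != "removed")
  if (length(vn)) {
    add(node_row[vn], node_row[vn] + n_act, "nodal", "lateral_vertical",
        paste0("nV:", vn), ifelse(nstate[vn] == "ablated", 0.01, 1), FALSE)
  }
  # nodal diagonals: one per apical edge i<j, apical i -> basal j
  keep <- !(fixed_node[et_a$i] & fixed_node[et_a$j])
  e <- et_a[keep, , drop = FALSE]
  if (nrow(e)) {
    add(node_row[e$i], node_row[e$j] + n_act, "nodal", "lateral_diagonal",
        paste0("nD:", e$i, "-", e$j), seg_scale_nodes(cbind(e$i, e$j)), FALSE)
  }

  # vertex in-layer: dual segment per interior triangulation edge
  all_fixed_triple <- function(tr_mat) apply(tr_mat, 1L, function(x) all(fixed_node[x]))
  for (lay in c("a", "b")) {
    et <- if (lay == "a") et_a else et_b
    tri <- if (lay == "a") tri_a else tri_b
    vmap <- if (lay == "a") vmap_a else vmap_b
    int_e <- et[!is.na(et$t2), , drop = FALSE]
    if (!nrow(int_e)) next
    t1k <- triangle_keys(tri[int_e$t1, , drop = FALSE])
    t2k <- triangle_keys(tri[int_e$t2, , drop = FALSE])
    p1 <- unname(vmap[paste0(lay, ":", t1k)])
    p2 <- unname(vmap[paste0(lay, ":", t2k)])
    inert <- all_fixed_triple(tri[int_e$t1, , drop = FALSE]) &
      all_fixed_triple(tri[int_e$t2, , drop = FALSE])
    keep <- !inert
    if (any(keep)) {
      kk <- paste0("v", toupper(lay), ":", pmin(t1k, t2k)[keep], "|", pmax(t1k, t2k)[keep])
      add(p1[keep], p2[keep], "vertex", if (lay == "a") "apical" else "basal",
          kk, seg_scale_nodes(cbind(int_e$i, int_e$j)[keep, , drop = FALSE]), TRUE)
    }
  }

  # lateral vertical vertex segments: matched triples in both layers
  ka <- triangle_keys(tri_a); kb <- triangle_keys(tri_b)
  common <- intersect(ka, kb)
  if (length(common)) {
    trs <- do.call(rbind, strsplit(common, "-"))
    trs <- matrix(as.integer(trs), ncol = 3L)
    keep <- !apply(trs, 1L, function(x) all(fixed_node[x]))
    common <- common[keep]; trs <- trs[keep, , drop = FALSE]
    if (length(common)) {
      add(unname(vmap_a[paste0("a:", common)]), unname(vmap_b[paste0("b:", common)]),
          "vertex", "lateral_vertical", paste0("vV:", common),
          seg_scale_nodes(trs), TRUE)
    }
  }
  # intermediate-vertex bridges: m to its 2 apical and 2 basal vertices
  for (m in inter) {
    mp <- free_row[[m$key]]
    for (w in 1:2) {
      ta <- paste(m$apical_triples[w, ], collapse = "-")
      add(unname(vmap_a[[paste0("a:", ta)]]), mp, "vertex", "lateral_vertical",
          paste0("vVm:", ta, ":a"), 1, TRUE)
      tb <- paste(m$basal_triples[w, ], collapse = "-")
      add(mp, unname(vmap_b[[paste0("b:", tb)]]), "vertex", "lateral_vertical",
          paste0("vVm:", tb, ":b"), 1, TRUE)
    }
  }

  # lateral diagonal vertex segments: fan edges of each face triangulation
  for (face in faces) {
    cyc <- face_cycle_any(face)
    if (length(cyc) < 4L) next  # triangles have no interior diagonal
    k <- order(pt_id[cyc])[1L]
    rot <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
    anchor <- rot[1L]
    others <- rot[-1L]
    diag_to <- others[-c(1L, length(others))]
    if (!length(diag_to)) next
    sc <- if (all(nstate[c(face$i, face$j)] == "ablated", na.rm = TRUE) &&
              all(ml$nodes$is_cell[c(face$i, face$j)])) 0.01 else 1
    add(rep(anchor, length(diag_to)), diag_to, "vertex", "lateral_diagonal",
        paste0("vD:", pt_id[anchor], "|", pt_id[diag_to]), sc, TRUE)
  }

  out <- do.call(rbind, segs)
  if (anyDuplicated(out$key)) out <- out[!duplicated(out$key), ]
  out$wound_apical <- FALSE
  out$wound_lateral <- FALSE
  tibble::as_tibble(out)
}

# face cycle in an arbitrary (but deterministic) traversal; used for fan
# triangulation and diagonal creation, identical for both adjacent cells
face_cycle_any <- function(face) {
  if (length(face$ap_pts) == 2L) {
    face_cycle(face, face$ap_pts[1L], face$ap_pts[2L], "a")
  } else {
    face_cycle(face, face$bs_pts[1L], face$bs_pts[2L], "b")
  }
}

# ---- volume tetrahedralization ---------------------------------------------

build_tets <- function(cells, faces, node_row, n_act, pt_id) {
  tet_list <- list()
  cell_list <- list()
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    la <- cl$loop_a; lb <- cl$loop_b
    pa <- node_row[cl$node]          # apical node point
    pb <- node_row[cl$node] + n_act  # basal node point
    # apical cap: fan from apical node point (outward +z): (xA, v_i, v_{i+1})
    nxt_a <- c(la[-1L], la[1L])
    capA <- cbind(pa, la, nxt_a)
    # basal cap: outward -z -> reversed
    nxt_b <- c(lb[-1L], lb[1L])
    capB <- cbind(pb, nxt_b, lb)
    tris <- rbind(capA, capB)
    # lateral faces in apical loop order
    p <- length(la)
    for (i in seq_len(p)) {
      nb <- cl$nb_a[i]
      face <- faces[[paste(min(cl$node, nb), max(cl$node, nb))]]
      cyc <- face_cycle(face, la[i], la[if (i == p) 1L else i + 1L], "a")
      tris <- rbind(tris, fan_triangles(cyc, rev = TRUE, pt_id = pt_id))
    }
    # basal-only faces (junctions present basally but not apically)
    extra <- setdiff(cl$nb_b, cl$nb_a)
    q <- length(lb)
    for (nb in extra) {
      i <- which(cl$nb_b == nb)
      face <- faces[[paste(min(cl$node, nb), max(cl$node, nb))]]
      # basal edge traversed in reverse basal loop order for outward normals
      cyc <- face_cycle(face, lb[if (i == q) 1L else i + 1L], lb[i], "b")
      tris <- rbind(tris, fan_triangles(cyc, rev = FALSE, pt_id = pt_id))
    }
    tet_list[[k]] <- cbind(cl$mid, tris)
    cell_list[[k]] <- rep(k, nrow(tris))
  }
  tets <- do.call(rbind, tet_list)
  storage.mode(tets) <- "integer"
  list(tets = tets, tet_cell = unlist(cell_list))
}

# fan triangulation of a polygon cycle from a canonical anchor (smallest
# stable point identity, shared by both incident cells); rev flips orientation
fan_triangles <- function(cyc, rev = FALSE, pt_id = NULL) {
  k <- if (is.null(pt_id)) which.min(cyc) else order(pt_id[cyc])[1L]
  rot <- c(cyc[k:length(cyc)], cyc[seq_len(k - 1L)])
  n <- length(rot)
  tri <- cbind(rot[1L], rot[2:(n - 1L)], rot[3:n])
  if (rev) tri <- tri[, c(1L, 3L, 2L), drop = FALSE]
  tri
}

# ---- positions and volumes --------------------------------------------------

#' Current degree-of-freedom positions of a monolayer
#' @param ml a `monolayer`.
#' @return numeric matrix (n_dof x 3): apical nodes, basal nodes, free vertices.
#' @export
ml_dof_positions <- function(ml) {
  topo <- ml$topo
  rbind(ml$xa[topo$act, , drop = FALSE],
        ml$xb[topo$act, , drop = FALSE],
        as.matrix(ml$free_verts[, c("x", "y", "z")]))
}

# write dof positions back into the monolayer stores
ml_set_dof_positions <- function(ml, Xd) {
  topo <- ml$topo
  n <- topo$n_act
  ml$xa[topo$act, ] <- Xd[seq_len(n), , drop = FALSE]
  ml$xb[topo$act, ] <- Xd[n + seq_len(n), , drop = FALSE]
  if (nrow(ml$free_verts)) {
    ml$free_verts[, c("x", "y", "z")] <- as.data.frame(Xd[2L * n + seq_len(nrow(ml$free_verts)), , drop = FALSE])
  }
  ml
}

#' All point positions (nodes, vertices, cell midpoints)
#'
#' Constrained vertices are evaluated from the barycentric interpolation of
#' their parent triangle's nodes (equal weights 1/3), so the kinematic
#' constraint holds exactly whenever this function is used.
#' @param ml a `monolayer`.
#' @return numeric matrix (n_pts x 3).
#' @export
ml_points <- function(ml) {
  as.matrix(ml$topo$S %*% ml_dof_positions(ml))
}

#' Interpolated vertex positions
#'
#' Returns the vertex table with positions set from the cell-center
#' interpolation for constrained vertices; relaxed and intermediate vertices
#' carry their own coordinates.
#' @param ml a `monolayer`.
#' @return tibble of vertices with `x`, `y`, `z`.
#' @export
interpolate_vertices <- function(ml) {
  Xp <- ml_points(ml)
  v <- ml$topo$verts
  v$x <- Xp[v$point, 1L]; v$y <- Xp[v$point, 2L]; v$z <- Xp[v$point, 3L]
  v
}

# lengths of all segments at current positions
segment_lengths <- function(ml, Xp = NULL) {
  if (is.null(Xp)) Xp <- ml_points(ml)
  s <- ml$topo$segments
  sqrt(rowSums((Xp[s$p1, , drop = FALSE] - Xp[s$p2, , drop = FALSE])^2))
}

#' Cell volumes by signed tetrahedron decomposition
#'
#' Each cell's surface (apical cap fanned from the apical node, basal cap from
#' the basal node, lateral faces fanned from a canonical anchor along the
#' stored diagonals) is coned to the cell midpoint (xA+xB)/2; the signed
#' tetrahedron volumes sum to the cell volume.
#'
#' @param ml a `monolayer`.
#' @param cell_ids optional node ids of cells; default all non-removed cells.
#' @return named numeric vector of volumes (um^3).
#' @export
cell_volumes <- function(ml, cell_ids = NULL, Xp = NULL) {
  topo <- ml$topo
  if (is.null(Xp)) Xp <- ml_points(ml)
  tets <- topo$tets
  a <- Xp[tets[, 1L], , drop = FALSE]; b <- Xp[tets[, 2L], , drop = FALSE]
  c_ <- Xp[tets[, 3L], , drop = FALSE]; d <- Xp[tets[, 4L], , drop = FALSE]
  v6 <- tet_det(b - a, c_ - a, d - a)
  vols <- as.numeric(rowsum(v6, topo$tet_cell) / 6)
  names(vols) <- names(topo$cells)[sort(unique(topo$tet_cell))]
  if (!is.null(cell_ids)) vols <- vols[as.character(cell_ids)]
  vols
}

#' Volume of one cell
#' @param ml a `monolayer`.
#' @param cell_id node id of the cell.
#' @param check error if the cell is degenerate (volume <= 0) and alive.
#' @return scalar volume (um^3).
#' @export
cell_volume <- function(ml, cell_id, check = FALSE) {
  v <- unname(cell_volumes(ml, cell_id))
  if (check && v <= 0) stop("geometric failure: cell ", cell_id, " has volume <= 0")
  v
}

# fast 3x3 determinant for row-matrices
tet_det <- function(u, v, w) {
  u[, 1L] * (v[, 2L] * w[, 3L] - v[, 3L] * w[, 2L]) -
    u[, 2L] * (v[, 1L] * w[, 3L] - v[, 3L] * w[, 1L]) +
    u[, 3L] * (v[, 1L] * w[, 2L] - v[, 2L] * w[, 1L])
}

# apical polygon area of the k-th cell (projected along the apico-basal axis)
apical_cell_area <- function(ml, k, Xp = NULL) {
  if (is.null(Xp)) Xp <- ml_points(ml)
  loop <- ml$topo$cells[[k]]$loop_a
  shoelace_area(Xp[loop, 1L], Xp[loop, 2L])
}

# signed shoelace area (returns absolute value)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
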