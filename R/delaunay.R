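#' Delaunay triangulation of 2D points (Bowyer-Watson)
#'
#' Incremental Bowyer-Watson triangulation used to build the apical and basal
#' cell-center triangulations. Written for the modest point counts of
#' epithelial patches (tens to a few hundred cell centers); robustness for
#' near-cocircular configurations is handled with a relative tolerance on the
#' in-circumcircle predicate, so ties (e.g. a noise-free hexagonal lattice)
#' resolve to an arbitrary but valid diagonal.
#'
#' @param xy numeric matrix (n x 2) of point coordinates (micrometers).
#' @return integer matrix (n_tri x 3) of point indices, each triangle oriented
#'   counter-clockwise, rows in canonical (lexicographic) order.
#' @export
delaunay_triangulate <- function(xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 points to triangulate")
  if (anyDuplicated(round(xy, 9L)) > 0L) stop("duplicate points in triangulation input")
  ctr <- colMeans(xy)
  rel <- sweep(xy, 2L, ctr)
  # collinearity: all cross products against the longest spanning vector ~ 0
  v1 <- rel[which.max(rowSums(rel^2)), ]
  crosses <- rel[, 1L] * v1[2L] - rel[, 2L] * v1[1L]
  if (all(abs(crosses) < 1e-10 * (max(rowSums(rel^2)) + 1))) {
    stop("degenerate (collinear) point set: cannot triangulate")
  }

  span <- max(apply(xy, 2L, function(c) diff(range(c)))) + 1
  # super-triangle generously containing all points
  s1 <- ctr + c(-3e5 * span, -1e5 * span)
  s2 <- ctr + c(3e5 * span, -1e5 * span)
  s3 <- ctr + c(0, 3e5 * span)
  pts <- rbind(xy, s1, s2, s3)

  max_tri <- 4L * n + 16L
  tri <- matrix(0L, max_tri, 3L)
  ccx <- numeric(max_tri); ccy <- numeric(max_tri); r2 <- numeric(max_tri)
  alive <- logical(max_tri)
  m <- 0L

  add_tri <- function(a, b, c) {
    # orient CCW
    ax <- pts[a, 1L]; ay <- pts[a, 2L]
    bx <- pts[b, 1L]; by <- pts[b, 2L]
    cx <- pts[c, 1L]; cy <- pts[c, 2L]
    det <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    if (det < 0) { tmp <- b; b <- c; c <- tmp }
    cc <- circumcircle(pts[a, ], pts[b, ], pts[c, ])
    m <<- m + 1L
    if (m > nrow(tri)) { # grow storage
      tri <<- rbind(tri, matrix(0L, max_tri, 3L))
      ccx <<- c(ccx, numeric(max_tri)); ccy <<- c(ccy, numeric(max_tri))
      r2 <<- c(r2, numeric(max_tri)); alive <<- c(alive, logical(max_tri))
    }
    tri[m, ] <<- c(a, b, c)
    ccx[m] <<- cc[1L]; ccy[m] <<- cc[2L]; r2[m] <<- cc[3L]
    alive[m] <<- TRUE
    invisible(NULL)
  }

  add_tri(n + 1L, n + 2L, n + 3L)

  for (p in seq_len(n)) {
    px <- pts[p, 1L]; py <- pts[p, 2L]
    idx <- which(alive[seq_len(m)])
    d2 <- (ccx[idx] - px)^2 + (ccy[idx] - py)^2
    bad <- idx[d2 < r2[idx] * (1 - 1e-12) - 1e-300]
    if (length(bad) == 0L) stop("triangulation insertion failed (point outside all circumcircles)")
    # cavity boundary: edges of bad triangles occurring exactly once
    e <- rbind(tri[bad, c(1L, 2L), drop = FALSE],
               tri[bad, c(2L, 3L), drop = FALSE],
               tri[bad, c(3L, 1L), drop = FALSE])
    ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    once <- ekey %in% names(which(table(ekey) == 1L))
    alive[bad] <- FALSE
    eb <- e[once, , drop = FALSE]
    for (k in seq_len(nrow(eb))) add_tri(eb[k, 1L], eb[k, 2L], p)
  }

  keep <- which(alive[seq_len(m)])
  out <- tri[keep, , drop = FALSE]
  out <- out[rowSums(out > n) == 0L, , drop = FALSE]
  canonical_triangles(out, xy)
}

# circumcircle of triangle: returns c(cx, cy, radius^2)
circumcircle <- function(a, b, c) {
  ax <- a[1L]; ay <- a[2L]; bx <- b[1L]; by <- b[2L]; cx <- c[1L]; cy <- c[2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14 * (abs(ax) + abs(bx) + abs(cx) + 1)^2) {
    return(c(mean(c(ax, bx, cx)), mean(c(ay, by, cy)), Inf))
  }
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# canonical representation: CCW orientation w.r.t. xy, rows start at smallest
# index, rows sorted lexicographically. Makes triangulations comparable.
canonical_triangles <- function(tri, xy) {
  tri <- t(apply(tri, 1L, function(t3) {
    i <- which.min(t3)
    t3 <- t3[((i - 1L + 0L:2L) %% 3L) + 1L]
    a <- xy[t3[1L], ]; b <- xy[t3[2L], ]; c <- xy[t3[3L], ]
    if ((b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L]) < 0) {
      t3 <- t3[c(1L, 3L, 2L)]
    }
    t3
  }))
  tri <- tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
  storage.mode(tri) <- "integer"
  tri
}

# sorted-triple string keys for triangles, used as stable vertex identities
triangle_keys <- function(tri) {
  s <- t(apply(tri, 1L, sort))
  paste(s[, 1L], s[, 2L], s[, 3L], sep = "-")
}

# edge table of a triangulation: one row per undirected edge i<j with the one
# or two incident triangles and their opposite vertices
tri_edge_table <- function(tri) {
  m <- nrow(tri)
  e <- rbind(tri[, c(1L, 2L, 3L), drop = FALSE],
             tri[, c(2L, 3L, 1L), drop = FALSE],
             tri[, c(3L, 1L, 2L), drop = FALSE])
  tid <- rep.int(seq_len(m), 3L)
  i <- pmin(e[, 1L], e[, 2L]); j <- pmax(e[, 1L], e[, 2L])
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; opp <- e[ord, 3L]; tid <- tid[ord]
  key <- paste(i, j)
  first <- !duplicated(key)
  idx <- cumsum(first)
  ne <- sum(first)
  out <- data.frame(i = i[first], j = j[first],
                    t1 = NA_integer_, t2 = NA_integer_,
                    opp1 = NA_integer_, opp2 = NA_integer_)
  second <- duplicated(key)
  out$t1 <- tid[first]; out$opp1 <- opp[first]
  out$t2[idx[second]] <- tid[second]
  out$opp2[idx[second]] <- opp[second]
  if (anyDuplicated(key) && any(table(key) > 2L)) stop("non-manifold triangulation")
  out
}

# node adjacency (edge-connected neighbours) from a triangulation
delaunay_adjacency <- function(tri, n_nodes) {
  et <- tri_edge_table(tri)
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(et))) {
    adj[[et$i[k]]] <- c(adj[[et$i[k]]], et$j[k])
    adj[[et$j[k]]] <- c(adj[[et$j[k]]], et$i[k])
  }
  lapply(adj, unique)
}

# is a set of nodes edge-connected in the triangulation? (breadth-first search)
nodes_connected <- function(tri, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) <= 1L) return(TRUE)
  adj <- delaunay_adjacency(tri, max(tri))
  seen <- nodes[1L]
  frontier <- nodes[1L]
  while (length(frontier) > 0L) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier])), nodes), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(nodes)
}

# Retriangulate the star-shaped hole left by deleting one node.
# ring: the node's neighbours in CCW order around it. Returns triangles (rows
# of node indices) filling the hole, chosen by repeated best-aspect ear
# clipping (subsequent aspect-gated flipping cleans up further).
retriangulate_hole <- function(ring, xy) {
  stopifnot(length(ring) >= 3L)
  tris <- matrix(0L, 0L, 3L)
  poly <- ring
  while (length(poly) > 3L) {
    np <- length(poly)
    best <- NA_integer_; best_r <- Inf
    for (k in seq_len(np)) {
      a <- poly[((k - 2L) %% np) + 1L]
      b <- poly[k]
      c <- poly[(k %% np) + 1L]
      pa <- xy[a, ]; pb <- xy[b, ]; pc <- xy[c, ]
      det <- (pb[1L] - pa[1L]) * (pc[2L] - pa[2L]) - (pb[2L] - pa[2L]) * (pc[1L] - pa[1L])
      if (det <= 0) next  # reflex corner, not an ear
      others <- setdiff(poly, c(a, b, c))
      if (length(others) > 0L && any(points_in_triangle(xy[others, , drop = FALSE], pa, pb, pc))) next
      r <- aspect_ratio_xy(pa, pb, pc)
      if (r < best_r) { best_r <- r; best <- k }
    }
    if (is.na(best)) {
      # geometrically tangled ring (deep inside a collapsing wound): fall
      # back to a plain fan in ring order; later flips restore quality
      tris <- rbind(tris, cbind(poly[1L], poly[2:(length(poly) - 1L)], poly[3:length(poly)]))
      storage.mode(tris) <- "integer"
      return(tris)
    }
    np <- length(poly)
    a <- poly[((best - 2L) %% np) + 1L]; b <- poly[best]; c <- poly[(best %% np) + 1L]
    tris <- rbind(tris, c(a, b, c))
    poly <- poly[-best]
  }
  tris <- rbind(tris, poly)
  storage.mode(tris) <- "integer"
  tris
}

points_in_triangle <- function(p, a, b, c) {
  s1 <- (b[1L] - a[1L]) * (p[, 2L] - a[2L]) - (b[2L] - a[2L]) * (p[, 1L] - a[1L])
  s2 <- (c[1L] - b[1L]) * (p[, 2L] - b[2L]) - (c[2L] - b[2L]) * (p[, 1L] - b[1L])
  s3 <- (a[1L] - c[1L]) * (p[, 2L] - c[2L]) - (a[2L] - c[2L]) * (p[, 1L] - c[1L])
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}

aspect_ratio_xy <- function(a, b, c) {
  e <- sqrt(c(sum((a - b)^2), sum((b - c)^2), sum((c - a)^2)))
  if (min(e) <= 0) return(Inf)
  max(e) / min(e)
}
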