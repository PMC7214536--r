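#' Aspect-ratio-gated Lawson flipping toward the Delaunay criterion
#'
#' Candidate flips are interior edges violating the in-circumcircle
#' (local Delaunay) test. A candidate is accepted iff the worst
#' longest/shortest-edge aspect ratio of the two post-flip triangles
#' satisfies r_new < (1 + tol_r) * r_old, where r_old is the worst pre-flip
#' aspect ratio: small tol_r leaves stretched (suboptimal) triangles in
#' place near strongly deformed regions, larger values flip more freely. At
#' tol_r = 0 the gate is bypassed entirely and plain Lawson flipping runs to
#' its fixed point, which is the standard Delaunay triangulation of the
#' projected points.
#'
#' @param tri triangulation (n_tri x 3 integer matrix).
#' @param xy projected node positions (the apico-basal coordinate dropped).
#' @param tol_r non-negative aspect-ratio tolerance.
#' @param max_flips flip budget guarding against cycling.
#' @return the re-triangulated matrix (canonical form).
#' @export
propose_flips <- function(tri, xy, tol_r = 0.1, max_flips = 10L * nrow(tri)) {
  n_flips <- 0L
  repeat {
    fl <- find_flip(tri, xy, tol_r)
    if (is.null(fl)) break
    tri <- fl$tri
    n_flips <- n_flips + 1L
    if (n_flips > max_flips) stop("remeshing did not reach a fixed point (flip budget exhausted)")
  }
  canonical_triangles(tri, xy)
}

# one accepted flip (or NULL at the fixed point); skip_keys are edge keys
# "i j" excluded from flipping (used to blacklist unresolvable flips)
find_flip <- function(tri, xy, tol_r, skip_keys = character(0)) {
  et <- tri_edge_table(tri)
  interior <- which(!is.na(et$t2))
  if (!length(interior)) return(NULL)
  viol <- interior[incircle_violated_vec(xy, et$i[interior], et$j[interior],
                                         et$opp1[interior], et$opp2[interior])]
  for (e in viol) {
    i <- et$i[e]; j <- et$j[e]; k <- et$opp1[e]; l <- et$opp2[e]
    key <- paste(i, j)
    if (key %in% skip_keys) next
    # flip validity: i and j on opposite sides of line k-l, and edge {k,l}
    # not already in the triangulation
    s1 <- side_of(xy[k, ], xy[l, ], xy[i, ])
    s2 <- side_of(xy[k, ], xy[l, ], xy[j, ])
    if (s1 * s2 >= 0) next
    if (any((et$i == min(k, l)) & (et$j == max(k, l)))) next
    if (tol_r > 0) {
      r_old <- max(aspect_ratio_xy(xy[i, ], xy[j, ], xy[k, ]),
                   aspect_ratio_xy(xy[i, ], xy[j, ], xy[l, ]))
      r_new <- max(aspect_ratio_xy(xy[i, ], xy[k, ], xy[l, ]),
                   aspect_ratio_xy(xy[j, ], xy[k, ], xy[l, ]))
      if (!(r_new < (1 + tol_r) * r_old)) next
    }
    newtri <- rbind(tri[-c(et$t1[e], et$t2[e]), , drop = FALSE],
                    flip_pair(tri[et$t1[e], ], i, j, k, l))
    return(list(tri = newtri, edge = c(i, j), new_edge = c(k, l)))
  }
  NULL
}

# combinatorially consistent orientation of the two post-flip triangles,
# inherited from the orientation of the old triangle containing edge {i,j}
# (robust even when deformed triangles are geometrically inverted)
flip_pair <- function(t1, i, j, k, l) {
  # does t1 contain the directed edge i -> j?
  pos_i <- which(t1 == i)
  fwd <- t1[(pos_i %% 3L) + 1L] == j
  # t1 contains k or l as its opposite vertex; normalize so `k` is t1's
  if (!(k %in% t1)) { tmp <- k; k <- l; l <- tmp }
  if (fwd) rbind(c(i, l, k), c(j, k, l)) else rbind(c(i, k, l), c(j, l, k))
}

# is point d strictly inside the circumcircle of CCW triangle (a,b,c)?
incircle_violated <- function(a, b, c, d) {
  incircle_violated_vec(rbind(a, b, c, d), 1L, 2L, 3L, 4L)
}

# vectorized in-circumcircle predicate over edge lists (i,j) with opposite
# vertices k (triangle member) and l (tested point)
incircle_violated_vec <- function(xy, i, j, k, l) {
  ax <- xy[i, 1L] - xy[l, 1L]; ay <- xy[i, 2L] - xy[l, 2L]
  bx <- xy[j, 1L] - xy[l, 1L]; by <- xy[j, 2L] - xy[l, 2L]
  cx <- xy[k, 1L] - xy[l, 1L]; cy <- xy[k, 2L] - xy[l, 2L]
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  det3 <- ax * (by * c2 - b2 * cy) - ay * (bx * c2 - b2 * cx) + a2 * (bx * cy - by * cx)
  # sign convention depends on orientation of (i,j,k)
  orient <- (xy[j, 1L] - xy[i, 1L]) * (xy[k, 2L] - xy[i, 2L]) -
    (xy[j, 2L] - xy[i, 2L]) * (xy[k, 1L] - xy[i, 1L])
  scale <- (pmax(abs(ax), abs(ay), abs(bx), abs(by), abs(cx), abs(cy)))^4 + 1e-300
  ifelse(orient >= 0, det3, -det3) > 1e-9 * scale
}

side_of <- function(a, b, p) {
  (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
}

orient_ccw <- function(t3, xy) {
  if (side_of(xy[t3[1L], ], xy[t3[2L], ], xy[t3[3L], ]) < 0) t3 <- t3[c(1L, 3L, 2L)]
  t3
}

#' Apply a layer connectivity change to a monolayer
#'
#' Replaces one layer's triangulation and rebuilds the derived topology:
#' vertices of deleted triangles are removed, vertices of created triangles
#' instantiated (at barycenters, or as free intermediate vertices where the
#' layers now disagree), cell loops and lateral faces rebuilt, and affected
#' segments reborn stress-free while untouched segments keep their rest
#' lengths.
#'
#' @param ml a `monolayer`.
#' @param new_tri the new triangulation of the layer.
#' @param layer `"apical"` or `"basal"`.
#' @return updated monolayer.
#' @export
apply_connectivity_change <- function(ml, new_tri, layer = c("apical", "basal")) {
  layer <- match.arg(layer)
  old <- if (layer == "apical") ml$tri_a else ml$tri_b
  if (identical(canonical_triangles(old, ml$xa[, 1:2]),
                canonical_triangles(new_tri, ml$xa[, 1:2]))) {
    return(ml)  # no-op change
  }
  if (layer == "apical") ml$tri_a <- new_tri else ml$tri_b <- new_tri
  rebuild_topology(ml)
}

#' Reconcile intermediate vertices with the current layer topologies
#'
#' Rebuilds the derived topology so that every cell whose apical and basal
#' loops disagree is stitched through intermediate vertices (one per flipped
#' quad), and intermediate vertices whose mismatch has been restored are
#' removed with their incident vertical segments merged (rest lengths
#' summed). With matching loops this is the identity.
#'
#' @param ml a `monolayer`.
#' @return updated monolayer.
#' @export
reconcile_intermediate_vertices <- function(ml) {
  rebuild_topology(ml)
}

#' One remeshing pass after a converged step
#'
#' Runs aspect-gated Lawson flipping independently on the apical and basal
#' triangulations (projected along the apico-basal axis). Each accepted flip
#' is checked for intermediate-vertex resolvability; a flip that would leave
#' the two layers in an unstitchable state triggers the matching flip in the
#' opposite layer (synchronised T1) when possible, and is otherwise reverted.
#'
#' @param ml a `monolayer`.
#' @param tol_r aspect-ratio tolerance.
#' @param force_equal_layers keep the two triangulations identical: every
#'   accepted flip is applied to both layers (pure-prism mode, no
#'   intermediate vertices are ever created).
#' @param t1_frac junction-collapse threshold: an in-layer vertex junction
#'   shorter than `t1_frac` times the mean initial junction length forces a
#'   neighbour exchange (T1) of its dual edge. This realizes intercalation
#'   at the wound edge, where crushed junctions connect relaxed vertices
#'   that the node-based Delaunay criterion cannot see. 0 disables.
#' @param flip_cooldown minutes during which an edge created by a flip may
#'   not flip back (hysteresis against flip chatter; stress-free rebirth of
#'   flipped segments shifts the equilibrium after every exchange).
#' @return updated monolayer (topology rebuilt if anything changed).
#' @export
remesh_step <- function(ml, tol_r = 0.1, force_equal_layers = FALSE,
                        t1_frac = 0.1, flip_cooldown = 3) {
  changed <- FALSE
  budget <- 10L * (nrow(ml$tri_a) + nrow(ml$tri_b))
  nfl <- 0L
  # hysteresis: an edge created by a recent flip may not flip back until the
  # cooldown has passed, damping flip chatter near the soft wound where
  # stress-free segment rebirth shifts the equilibrium after every exchange
  rf <- ml$recent_flips
  if (is.null(rf) || !length(rf)) rf <- stats::setNames(numeric(0), character(0))
  rf <- rf[rf > ml$time - flip_cooldown]
  record_flip <- function(layer, edge) {
    rf[paste0(layer, ":", min(edge), "-", max(edge))] <<- ml$time
  }
  cooled <- function(layer) {
    if (!length(rf)) return(character(0))
    keys <- names(rf)[startsWith(names(rf), paste0(layer, ":"))]
    sub("^[ab]:", "", gsub("-", " ", keys))
  }
  # accept one flip in `layer`, synchronising or reverting if the layers
  # would become unstitchable; returns TRUE if applied
  try_flip <- function(fl, layer) {
    tri_a <- if (layer == "a") fl$tri else ml$tri_a
    tri_b <- if (layer == "b") fl$tri else ml$tri_b
    if (force_equal_layers) {
      tri_a <- fl$tri; tri_b <- fl$tri
      det <- list(unresolved = NULL)
    } else {
      det <- tryCatch(detect_intermediates(tri_a, tri_b), error = function(e) e)
    }
    ok <- !inherits(det, "error") && is.null(det$unresolved)
    if (!ok && !force_equal_layers) {
      other_tri <- if (layer == "a") tri_b else tri_a
      other_xy <- if (layer == "a") ml$xb[, 1:2] else ml$xa[, 1:2]
      sync <- force_matching_flip(other_tri, other_xy, fl$edge, fl$new_edge)
      if (!is.null(sync)) {
        if (layer == "a") tri_b <- sync else tri_a <- sync
        det <- tryCatch(detect_intermediates(tri_a, tri_b), error = function(e) e)
        ok <- !inherits(det, "error") && is.null(det$unresolved)
      }
    }
    if (ok) {
      ml$tri_a <<- tri_a
      ml$tri_b <<- tri_b
      changed <<- TRUE
      record_flip(layer, fl$new_edge)
    }
    ok
  }
  for (layer in c("a", "b")) {
    skip <- cooled(layer)
    repeat {
      tri <- if (layer == "a") ml$tri_a else ml$tri_b
      xy <- if (layer == "a") ml$xa[, 1:2] else ml$xb[, 1:2]
      fl <- find_flip(tri, xy, tol_r, skip_keys = skip)
      if (is.null(fl)) break
      nfl <- nfl + 1L
      if (nfl > budget) stop("remeshing did not reach a fixed point (flip budget exhausted)")
      if (!try_flip(fl, layer)) skip <- c(skip, paste(fl$edge[1L], fl$edge[2L]))
    }
  }
  if (changed) {
    ml <- rebuild_topology(ml)
    changed <- FALSE
  }
  # junction-collapse T1s
  if (t1_frac > 0 && !is.null(ml$topo)) {
    thresh <- t1_frac * mean_junction_length(ml)
    for (pass in 1:8) {
      fl <- find_collapsed_junction(ml, thresh)
      if (is.null(fl)) break
      if (!try_flip(fl$flip, fl$layer)) break
      ml <- rebuild_topology(ml)  # lengths must refresh before the next pass
      changed <- FALSE
    }
  }
  if (changed) ml <- rebuild_topology(ml)
  ml$recent_flips <- rf
  ml
}

# mean initial in-plane junction length (from the reference lattice spacing)
mean_junction_length <- function(ml) {
  if (!is.null(ml$wound$init_junction_len)) return(ml$wound$init_junction_len)
  s <- ml$topo$segments
  sel <- s$network == "vertex" & s$orientation %in% c("apical", "basal")
  mean(s$L0[sel])
}

# find one in-layer vertex junction collapsed below `thresh` whose dual node
# edge can be flipped (neighbour exchange); after_change forces a topology
# rebuild beforehand so lengths are current
find_collapsed_junction <- function(ml, thresh) {
  s <- ml$topo$segments
  l <- segment_lengths(ml)
  sel <- which(s$network == "vertex" & s$orientation %in% c("apical", "basal") &
                 l < thresh)
  if (!length(sel)) return(NULL)
  sel <- sel[order(l[sel])]
  for (k in sel) {
    layer <- if (s$orientation[k] == "apical") "a" else "b"
    tri <- if (layer == "a") ml$tri_a else ml$tri_b
    xy <- if (layer == "a") ml$xa[, 1:2] else ml$xb[, 1:2]
    # dual edge: intersection of the two endpoint triangle keys
    kk <- sub("^v[AB]:", "", s$key[k])
    triples <- strsplit(strsplit(kk, "|", fixed = TRUE)[[1L]], "-")
    if (length(triples) != 2L) next
    shared <- intersect(as.integer(triples[[1L]]), as.integer(triples[[2L]]))
    if (length(shared) != 2L) next
    et <- tri_edge_table(tri)
    e <- which(et$i == min(shared) & et$j == max(shared))
    if (length(e) != 1L || is.na(et$t2[e])) next
    i <- et$i[e]; j <- et$j[e]; opp_k <- et$opp1[e]; opp_l <- et$opp2[e]
    if (any((et$i == min(opp_k, opp_l)) & (et$j == max(opp_k, opp_l)))) next
    newtri <- rbind(tri[-c(et$t1[e], et$t2[e]), , drop = FALSE],
                    flip_pair(tri[et$t1[e], ], i, j, opp_k, opp_l))
    return(list(flip = list(tri = newtri, edge = c(i, j), new_edge = c(opp_k, opp_l)),
                layer = layer))
  }
  NULL
}

# perform the same edge flip (old_edge -> new_edge) in a triangulation if it
# is present and geometrically valid; NULL otherwise
force_matching_flip <- function(tri, xy, old_edge, new_edge) {
  et <- tri_edge_table(tri)
  e <- which(et$i == min(old_edge) & et$j == max(old_edge))
  if (length(e) != 1L || is.na(et$t2[e])) return(NULL)
  if (!setequal(c(et$opp1[e], et$opp2[e]), new_edge)) return(NULL)
  i <- et$i[e]; j <- et$j[e]; k <- et$opp1[e]; l <- et$opp2[e]
  s1 <- side_of(xy[k, ], xy[l, ], xy[i, ])
  s2 <- side_of(xy[k, ], xy[l, ], xy[j, ])
  if (s1 * s2 >= 0) return(NULL)
  if (any((et$i == min(k, l)) & (et$j == max(k, l)))) return(NULL)
  rbind(tri[-c(et$t1[e], et$t2[e]), , drop = FALSE],
        flip_pair(tri[et$t1[e], ], i, j, k, l))
}
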