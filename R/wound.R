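#' Wound protocol: ablation and contractility schedules
#'
#' Describes the in silico laser ablation and the time-dependent purse-string
#' contractility. At `t_ablate = 0` the ablated cells' segments are softened
#' to `stiffness_factor` of their stiffness and their volume penalty removed.
#' From `t_w` on, wound-edge apical vertex segments receive the decaying
#' apical contractility `Y_Ac * (1 - (t - t_w)/decay_span)` (clamped at zero)
#' and wound-edge lateral vertex segments the constant `Y_Lc`, mimicking the
#' measured decay of purse-string Myosin II.
#'
#' @param ablated_cell_ids node ids of the cells to ablate (interior,
#'   edge-connected).
#' @param Y_Ac apical purse-string contractility amplitude (dimensionless).
#' @param Y_Lc lateral contractility amplitude (dimensionless).
#' @param t_w activation time of purse-string contractility (min).
#' @param decay_span span of the linear apical decay (min).
#' @param stiffness_factor residual stiffness fraction of ablated-cell
#'   segments, in (0, 1).
#' @param removal_area_fraction a degraded cell is removed (extruded) once
#'   the purse string has compressed its apical polygon below this fraction
#'   of the cell's own pre-ablation area (default 0.8, i.e. a 20%
#'   compression beyond undoing the recoil expansion — extrusion follows
#'   substantial apical constriction, not noise-level squeezing).
#'   Progressive removal is what lets the purse string ratchet the wound
#'   closed; removal only operates after the purse string activates at
#'   `t_w`.
#' @param closure_area_fraction the wound is declared closed once its apical
#'   area falls below this fraction of the post-recoil maximum.
#' @return object of class `wound_protocol`.
#' @export
wound_protocol <- function(ablated_cell_ids, Y_Ac = 2.3, Y_Lc = 0,
                           t_w = 6, decay_span = 400, stiffness_factor = 0.01,
                           removal_area_fraction = 0.8,
                           closure_area_fraction = 0.02) {
  stopifnot(stiffness_factor > 0, stiffness_factor < 1,
            Y_Ac >= 0, Y_Lc >= 0, t_w >= 0, decay_span > 0)
  structure(list(ablated_cell_ids = as.integer(ablated_cell_ids),
                 Y_Ac = Y_Ac, Y_Lc = Y_Lc, t_w = t_w,
                 decay_span = decay_span, stiffness_factor = stiffness_factor,
                 removal_area_fraction = removal_area_fraction,
                 closure_area_fraction = closure_area_fraction,
                 t_ablate = 0),
            class = "wound_protocol")
}

#' Wound-edge contractility schedule
#'
#' Returns `(Y_hat_A, Y_hat_L)` at time t: zero before `t_w`; afterwards the
#' apical value ramps down linearly over `decay_span` minutes (clamped at
#' zero) while the lateral value is constant.
#'
#' @param t time since ablation (min).
#' @param protocol a [wound_protocol()].
#' @return numeric length-2 vector `c(apical, lateral)`.
#' @export
contractility_schedule <- function(t, protocol) {
  if (t <= protocol$t_w) return(c(0, 0))
  c(max(0, protocol$Y_Ac * (1 - (t - protocol$t_w) / protocol$decay_span)),
    protocol$Y_Lc)
}

#' Ablate cells of a monolayer
#'
#' Marks the protocol's cells as ablated: every segment all of whose parent
#' cells are ablated has its stiffness scaled by `stiffness_factor`
#' (segments shared with a live cell keep full stiffness), the volume
#' penalty is removed from ablated cells, and all vertices on the wound-edge
#' interface are released from the barycentric constraint (relaxed degrees
#' of freedom, preventing zig-zag artifacts at the wound edge).
#'
#' @param ml a `monolayer`.
#' @param protocol a [wound_protocol()].
#' @return wounded monolayer.
#' @export
ablate <- function(ml, protocol) {
  ids <- protocol$ablated_cell_ids
  if (!length(ids)) return(ml)
  if (!all(ml$nodes$is_cell[ids])) stop("ablated ids must be cells")
  if (any(ml$nodes$is_fixed[ids])) {
    stop("cannot ablate boundary-adjacent cells (their centers are fixed)")
  }
  if (!nodes_connected(ml$tri_a, ids)) stop("ablated set is not edge-connected")
  ml$nodes$state[ids] <- "ablated"
  ml$nodes$volume_penalty_on[ids] <- FALSE
  ml$wound$active <- TRUE
  ml$relaxed_keys <- union(ml$relaxed_keys, wound_edge_vertex_keys(ml))
  ml <- rebuild_topology(ml)
  ml$wound$max_area <- apical_wound_area(ml)
  ml
}

# vertex keys (both layers) of triangles containing at least one ablated and
# one non-ablated node: the wound-edge interface
wound_edge_vertex_keys <- function(ml) {
  abl <- which(ml$nodes$state == "ablated")
  if (!length(abl)) return(character(0))
  keys <- character(0)
  for (lay in c("a", "b")) {
    tri <- if (lay == "a") ml$tri_a else ml$tri_b
    n_abl <- matrix(tri %in% abl, ncol = 3L)
    mixed <- rowSums(n_abl) %in% 1:2
    keys <- c(keys, paste0(lay, ":", triangle_keys(tri[mixed, , drop = FALSE])))
  }
  keys
}

# refresh wound-edge membership flags of segments and cache the apical wound
# perimeter; called from rebuild_topology while a wound is active
refresh_wound_membership <- function(ml) {
  topo <- ml$topo
  s <- topo$segments
  s$wound_apical <- FALSE
  s$wound_lateral <- FALSE
  abl <- which(ml$nodes$state == "ablated")
  if (length(abl)) {
    alive <- function(x) ml$nodes$is_cell[x] & ml$nodes$state[x] == "alive"
    # apical purse-string: dual segments of alive--ablated apical edges
    et_a <- tri_edge_table(ml$tri_a)
    mixed <- !is.na(et_a$t2) &
      ((et_a$i %in% abl & alive(et_a$j)) | (et_a$j %in% abl & alive(et_a$i)))
    if (any(mixed)) {
      t1k <- triangle_keys(ml$tri_a[et_a$t1[mixed], , drop = FALSE])
      t2k <- triangle_keys(ml$tri_a[et_a$t2[mixed], , drop = FALSE])
      keys <- paste0("vA:", pmin(t1k, t2k), "|", pmax(t1k, t2k))
      s$wound_apical <- s$key %in% keys
    }
    # lateral contractility: vertical + diagonal vertex segments of
    # wound-edge lateral faces (faces between an alive and an ablated cell)
    wkeys <- character(0)
    for (face in topo$faces) {
      ij <- c(face$i, face$j)
      if (!(any(ij %in% abl) && any(alive(ij)))) next
      if (length(face$ap_pts) == 2L) {
        for (w in 1:2) {
          tr <- paste(face$ap_triples[w, ], collapse = "-")
          wkeys <- c(wkeys, paste0("vV:", tr), paste0("vVm:", tr, ":a"))
        }
      }
      if (length(face$bs_pts) == 2L) {
        for (w in 1:2) {
          tr <- paste(face$bs_triples[w, ], collapse = "-")
          wkeys <- c(wkeys, paste0("vV:", tr), paste0("vVm:", tr, ":b"))
        }
      }
      wkeys <- c(wkeys, grep(paste0("^vD:", face$key, ":"), s$key, value = TRUE))
    }
    s$wound_lateral <- s$key %in% wkeys & s$orientation %in%
      c("lateral_vertical", "lateral_diagonal") & s$network == "vertex"
    ml$topo$perimeter <- extract_perimeter(ml, s)
  } else {
    ml$topo$perimeter <- NULL
  }
  ml$topo$segments <- s
  ml
}

# ordered cycle(s) of apical perimeter vertex points from the purse-string
# segments; NULL if none
extract_perimeter <- function(ml, s) {
  per <- s[s$wound_apical, , drop = FALSE]
  if (!nrow(per)) return(NULL)
  edges <- cbind(per$p1, per$p2)
  cycles <- list()
  remaining <- seq_len(nrow(edges))
  while (length(remaining)) {
    e0 <- remaining[1L]
    cyc <- c(edges[e0, 1L], edges[e0, 2L])
    remaining <- remaining[-1L]
    repeat {
      nxt <- which(edges[remaining, 1L] == cyc[length(cyc)] |
                     edges[remaining, 2L] == cyc[length(cyc)])
      if (!length(nxt)) break
      e <- remaining[nxt[1L]]
      v <- setdiff(edges[e, ], cyc[length(cyc)])
      remaining <- remaining[-nxt[1L]]
      if (!length(v)) break  # duplicate edge; shouldn't happen
      if (v == cyc[1L]) break  # closed
      cyc <- c(cyc, v)
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  list(cycles = cycles, segment_keys = per$key)
}

#' Maintain the wound after a converged, remeshed step
#'
#' Removes degraded (ablated) cells whose apical polygon area has fallen
#' below `removal_area_fraction` of the initial mean cell area (their node
#' leaves both triangulations and the holes are re-triangulated), refreshes
#' wound-edge membership, and latches the closure flag once the apical wound
#' area drops below `closure_area_fraction` of the post-recoil maximum (or
#' no ablated cell remains).
#'
#' @param ml a `monolayer`.
#' @param protocol a [wound_protocol()].
#' @return updated monolayer.
#' @export
maintain_wound <- function(ml, protocol) {
  if (!ml$wound$active) return(ml)
  dirty <- FALSE
  # removal (extrusion) of squeezed degraded cells; a removal that would
  # leave the two layers unstitchable is deferred to a later step
  if (!isTRUE(ml$wound$closed) && ml$time >= protocol$t_w) {
    repeat {
      Xp <- ml_points(ml)
      removed_one <- FALSE
      for (k in seq_along(ml$topo$cells)) {
        cl <- ml$topo$cells[[k]]
        if (ml$nodes$state[cl$node] != "ablated") next
        area <- apical_cell_area(ml, k, Xp)
        if (area < protocol$removal_area_fraction * ml$nodes$A0[cl$node]) {
          ml2 <- tryCatch(rebuild_topology(remove_cell(ml, cl$node)),
                          error = function(e) NULL)
          if (!is.null(ml2)) {
            ml <- ml2
            dirty <- TRUE
            removed_one <- TRUE
            break  # topology changed: rescan with fresh indices
          }
        }
      }
      if (!removed_one) break
    }
  }
  # newly wound-edge vertices become relaxed
  new_relaxed <- setdiff(wound_edge_vertex_keys(ml), ml$relaxed_keys)
  if (length(new_relaxed)) {
    ml$relaxed_keys <- c(ml$relaxed_keys, new_relaxed)
    dirty <- TRUE
  }
  if (dirty) ml <- rebuild_topology(ml)
  # closure latch
  area <- apical_wound_area(ml)
  ml$wound$max_area <- max(ml$wound$max_area, area, na.rm = TRUE)
  if (!isTRUE(ml$wound$closed)) {
    none_left <- !any(ml$nodes$state == "ablated")
    if (none_left || area < protocol$closure_area_fraction * ml$wound$max_area) {
      ml$wound$closed <- TRUE
      ml$wound$closure_time <- ml$time
    }
  }
  ml
}

# remove one (degraded) cell: its node leaves both triangulations; the star
# holes are re-triangulated, identically in both layers when the neighbour
# rings agree
remove_cell <- function(ml, node) {
  # synchronise the two layers around the dying cell: force the matching
  # flip of any mismatched quad containing it, so both layers see the same
  # neighbour ring and receive the same hole fill
  det <- detect_intermediates(ml$tri_a, ml$tri_b)
  for (m in det$intermediates) {
    if (!(node %in% m$quad)) next
    # basal-adjacent pair = the pair shared by both basal-only triples
    bpair <- intersect(m$basal_triples[1, ], m$basal_triples[2, ])
    apair <- intersect(m$apical_triples[1, ], m$apical_triples[2, ])
    sync <- force_matching_flip(ml$tri_b, ml$xb[, 1:2], bpair, apair)
    if (!is.null(sync)) {
      ml$tri_b <- sync
    } else {
      sync <- force_matching_flip(ml$tri_a, ml$xa[, 1:2], apair, bpair)
      if (is.null(sync)) stop("cannot synchronise layers around cell ", node)
      ml$tri_a <- sync
    }
  }
  get_ring <- function(tri) {
    star <- star_walk(node, tri, NULL)
    uw <- t(vapply(star, function(r) {
      t3 <- tri[r, ]
      i <- which(t3 == node)
      t3[((i - 1L + 1L:2L) %% 3L) + 1L]
    }, integer(2L)))
    uw[, 1L]
  }
  ring_a <- get_ring(ml$tri_a)
  ring_b <- get_ring(ml$tri_b)
  fill_a <- retriangulate_hole(ring_a, ml$xa[, 1:2])
  # identical neighbour rings get the identical fill, so the removal does not
  # manufacture apical/basal mismatches
  same_ring <- length(ring_a) == length(ring_b) && setequal(ring_a, ring_b)
  fill_b <- if (same_ring) fill_a else retriangulate_hole(ring_b, ml$xb[, 1:2])
  drop_rows <- function(tri) {
    tri[!(tri[, 1L] == node | tri[, 2L] == node | tri[, 3L] == node), , drop = FALSE]
  }
  ml$tri_a <- rbind(drop_rows(ml$tri_a), fill_a)
  ml$tri_b <- rbind(drop_rows(ml$tri_b), fill_b)
  ml$nodes$state[node] <- "removed"
  ml$nodes$volume_penalty_on[node] <- FALSE
  ml
}
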