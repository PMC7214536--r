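#' Projected apical wound area
#'
#' Shoelace area of the ordered apical wound perimeter (the purse-string
#' polygon), projected along the apico-basal axis; 0 for a closed wound or an
#' unwounded monolayer. If the perimeter decomposes into several cycles their
#' areas are summed.
#'
#' @param ml a `monolayer`.
#' @param check_simple error (with a polyline dump) if the perimeter polygon
#'   self-intersects; off by default in the hot loop.
#' @return area (um^2).
#' @export
apical_wound_area <- function(ml, check_simple = FALSE) {
  if (!ml$wound$active || isTRUE(ml$wound$closed)) return(0)
  per <- ml$topo$perimeter
  if (is.null(per) || !length(per$cycles)) return(0)
  Xp <- ml_points(ml)
  total <- 0
  for (cyc in per$cycles) {
    if (length(cyc) < 3L) next
    x <- Xp[cyc, 1L]; y <- Xp[cyc, 2L]
    if (check_simple && polygon_self_intersects(x, y)) {
      stop("self-intersecting wound perimeter: ",
           paste(sprintf("(%.3f,%.3f)", x, y), collapse = " "))
    }
    total <- total + shoelace_area(x, y)
  }
  total * ml$scale^2
}

polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(seq_len(n), c(2:n, 1L))
  for (a in seq_len(n - 2L)) {
    for (b in (a + 1L):n) {
      if (abs(a - b) <= 1L || (a == 1L && b == n)) next
      if (segments_cross(x[seg[a, ]], y[seg[a, ]], x[seg[b, ]], y[seg[b, ]])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(xa, ya, xb, yb) {
  d <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- d(xb[1], yb[1], xb[2], yb[2], xa[1], ya[1])
  d2 <- d(xb[1], yb[1], xb[2], yb[2], xa[2], ya[2])
  d3 <- d(xa[1], ya[1], xa[2], ya[2], xb[1], yb[1])
  d4 <- d(xa[1], ya[1], xa[2], ya[2], xb[2], yb[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Relative height of the monolayer at the wound
#'
#' 1 - depth/reference_height, where depth is the apico-basal distance
#' between the reference apical level away from the wound (95th percentile of
#' apical vertex heights in an annulus 2-4 cell diameters from the wound
#' center, a deterministic surrogate for the line fitted across the highest
#' apical points either side of the wound) and the mean height of the wound
#' perimeter. Returns 1 for an unwounded or flat monolayer.
#'
#' @param ml a `monolayer`.
#' @param reference_height monolayer reference height (um, default 35).
#' @return dimensionless relative height (<= 1, clamped below at 0).
#' @export
relative_height <- function(ml, reference_height = 35) {
  stopifnot(reference_height > 0)
  reference_height <- reference_height / ml$scale
  per <- ml$topo$perimeter
  if (!ml$wound$active || is.null(per) || !length(per$cycles)) return(1)
  Xp <- ml_points(ml)
  pv <- unique(unlist(per$cycles))
  perim_z <- mean(Xp[pv, 3L])
  ctr <- colMeans(Xp[pv, 1:2, drop = FALSE])
  r_per <- mean(sqrt((Xp[pv, 1L] - ctr[1L])^2 + (Xp[pv, 2L] - ctr[2L])^2))
  diam <- 2 * sqrt(ml$wound$init_mean_area / pi)
  # apical vertices of live cells in the annulus
  va <- ml$topo$verts[ml$topo$verts$layer == "a", ]
  pz <- Xp[va$point, , drop = FALSE]
  dist <- sqrt((pz[, 1L] - ctr[1L])^2 + (pz[, 2L] - ctr[2L])^2) - r_per
  sel <- dist >= 2 * diam & dist <= 4 * diam
  if (!any(sel)) sel <- dist >= 2 * diam
  if (!any(sel)) return(1)
  ref_z <- stats::quantile(pz[sel, 3L], 0.95, names = FALSE)
  depth <- ref_z - perim_z
  max(0, min(1, 1 - depth / reference_height))
}

#' Wound-edge cell and junction counts
#'
#' Number of alive cells incident to the apical wound perimeter and number of
#' apical vertex segments composing it; `(0, 0)` once the wound has closed.
#'
#' @param ml a `monolayer`.
#' @return named integer vector `c(n_edge_cells, n_perimeter_junctions)`.
#' @export
wound_edge_counts <- function(ml) {
  per <- ml$topo$perimeter
  if (!ml$wound$active || isTRUE(ml$wound$closed) ||
      is.null(per) || !length(per$cycles)) {
    return(c(n_edge_cells = 0L, n_perimeter_junctions = 0L))
  }
  pv <- unique(unlist(per$cycles))
  n_cells <- 0L
  for (cl in ml$topo$cells) {
    if (ml$nodes$state[cl$node] != "alive") next
    if (any(cl$loop_a %in% pv)) n_cells <- n_cells + 1L
  }
  c(n_edge_cells = n_cells,
    n_perimeter_junctions = length(per$segment_keys))
}

#' Per-cell relative volume deviation statistics
#'
#' Mean and maximum of |V - V0| / V0 over alive, non-ablated cells. Used to
#' monitor the volume penalty (with the default weight the mean stays below
#' ~10% through a wounded run).
#'
#' @param ml a `monolayer`.
#' @return named numeric vector `c(mean, max)`.
#' @export
volume_deviation_stats <- function(ml) {
  alive <- vapply(ml$topo$cells, function(cl)
    ml$nodes$state[cl$node] == "alive", logical(1L))
  if (!any(alive)) return(c(mean = NA_real_, max = NA_real_))
  V <- cell_volumes(ml)[alive]
  V0 <- ml$nodes$V0[vapply(ml$topo$cells[alive], function(cl) cl$node, integer(1L))]
  dev <- abs(V - V0) / V0
  c(mean = mean(dev), max = max(dev))
}
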