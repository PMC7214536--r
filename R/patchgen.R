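#' Specify a synthetic epithelial patch
#'
#' Describes a jittered hexagonal lattice of cell centers emulating segmented
#' cell-center tables from columnar epithelia (e.g. the wing imaginal disc):
#' roughly uniform centers on a bounded square patch, mild positional noise,
#' identical apical and basal centers, monolayer height 35 um.
#'
#' @param n_cells number of cells (>= 7, so at least one interior cell).
#' @param spacing hexagonal lattice constant in um (center-to-center distance).
#'   The default of 12 um at the default 35 um height reproduces the
#'   operating point of the calibrated model (columnar cells about three
#'   times taller than wide): the junctional line tension set by the
#'   intrinsic contractility then matches the calibrated purse-string
#'   amplitudes of the wound protocol.
#' @param patch_side side of the square patch in um; derived from `n_cells`
#'   and `spacing` when `NULL`.
#' @param noise_amplitude jitter amplitude as a fraction of `spacing`, in
#'   [0, 0.5). Below 0.5 no two lattice centers can collide.
#' @param height initial monolayer height in um (apical minus basal plane).
#' @param seed integer seed owned by this patch; all randomness derives from it.
#' @return an object of class `patch_spec`.
#' @export
patch_spec <- function(n_cells, spacing = 12, patch_side = NULL,
                       noise_amplitude = 0.15, height = 35, seed = 1L) {
  stopifnot(is.numeric(n_cells), n_cells >= 7)
  if (!is.numeric(noise_amplitude) || noise_amplitude < 0 || noise_amplitude >= 0.5) {
    stop("noise_amplitude must be in [0, 0.5)")
  }
  stopifnot(spacing > 0, height > 0)
  if (is.null(patch_side)) {
    # hex lattice cell area = spacing^2 * sqrt(3)/2; the margin (5% linear
    # plus one lattice constant) keeps the clipped lattice above n_cells
    # sites even for small patches
    patch_side <- sqrt(n_cells * spacing^2 * sqrt(3) / 2) * 1.05 + spacing
  }
  structure(list(n_cells = as.integer(n_cells), spacing = spacing,
                 patch_side = patch_side, noise_amplitude = noise_amplitude,
                 height = height, seed = as.integer(seed)),
            class = "patch_spec")
}

#' Generate cell centers on a jittered hexagonal patch
#'
#' Lays a hexagonal lattice over a square of side `patch_side` centered at the
#' origin, keeps the `n_cells` lattice sites closest to the patch center among
#' those inside the square, and jitters each independently by a uniform draw
#' from a disc of radius `noise_amplitude * spacing`. Deterministic for a
#' fixed seed.
#'
#' @param spec a [patch_spec()].
#' @return tibble with columns `cell_id`, `x_um`, `y_um`.
#' @export
generate_hex_patch <- function(spec) {
  stopifnot(inherits(spec, "patch_spec"))
  a <- spec$spacing
  half <- spec$patch_side / 2
  dy <- a * sqrt(3) / 2
  rows <- seq(-ceiling(half / dy) - 1L, ceiling(half / dy) + 1L)
  pts <- do.call(rbind, lapply(rows, function(r) {
    off <- if (r %% 2 == 0) 0 else a / 2
    xs <- off + a * seq(-ceiling((half + a) / a) - 1L, ceiling((half + a) / a) + 1L)
    cbind(xs, r * dy)
  }))
  inside <- abs(pts[, 1L]) <= half & abs(pts[, 2L]) <= half
  pts <- pts[inside, , drop = FALSE]
  if (nrow(pts) < spec$n_cells) {
    stop(sprintf(
      "patch sizing error: only %d lattice sites fit a square of side %.3g um at spacing %.3g um (%d cells requested); increase patch_side or reduce spacing",
      nrow(pts), spec$patch_side, a, spec$n_cells))
  }
  d2 <- pts[, 1L]^2 + pts[, 2L]^2
  keep <- order(d2)[seq_len(spec$n_cells)]
  pts <- pts[sort(keep), , drop = FALSE]
  rng <- patch_rng(spec$seed)
  n <- nrow(pts)
  r <- spec$noise_amplitude * a * sqrt(rng(n))
  th <- 2 * pi * rng(n)
  tibble::tibble(cell_id = seq_len(n),
                 x_um = pts[, 1L] + r * cos(th),
                 y_um = pts[, 2L] + r * sin(th))
}

# A local seeded uniform generator; never touches the global RNG state.
patch_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    x
  }
}

#' Select a connected central region of cells for ablation
#'
#' Grows a region from the cell nearest the patch centroid, repeatedly adding
#' the closest-to-centroid cell that is Delaunay-adjacent to the region, so the
#' returned set is always edge-connected. Errors if the region would touch the
#' patch boundary (boundary cells are fixed and cannot be ablated).
#'
#' @param centers tibble of cell centers (`cell_id`, `x_um`, `y_um`).
#' @param n_ablate number of cells to ablate.
#' @return integer vector of `cell_id`s.
#' @export
select_ablation_region <- function(centers, n_ablate) {
  xy <- as.matrix(centers[, c("x_um", "y_um")])
  n <- nrow(xy)
  tri <- delaunay_triangulate(xy)
  hull_cells <- boundary_cells_of(tri, n)
  interior <- setdiff(seq_len(n), hull_cells)
  if (n_ablate < 1 || n_ablate >= length(interior)) {
    stop("n_ablate must satisfy 1 <= n_ablate < number of interior cells")
  }
  ctr <- colMeans(xy)
  d2 <- (xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2
  adj <- delaunay_adjacency(tri, n)
  region <- which.min(d2)
  while (length(region) < n_ablate) {
    cand <- setdiff(unique(unlist(adj[region])), region)
    region <- c(region, cand[which.min(d2[cand])])
  }
  if (any(region %in% hull_cells)) {
    stop("requested ablation region touches the patch boundary (boundary cells are fixed)")
  }
  sort(centers$cell_id[region])
}

# cells on the outer rim of a triangulated point set: incident to a hull edge
boundary_cells_of <- function(tri, n) {
  et <- tri_edge_table(tri)
  hull <- is.na(et$t2)
  sort(unique(c(et$i[hull], et$j[hull])))
}

#' Read / write cell-center tables
#'
#' CSV contract: header `cell_id,x_um,y_um`, '.' decimal separator.
#' @param path file path.
#' @param centers tibble of centers.
#' @name centers_io
#' @export
read_centers <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_integer(),
    x_um = readr::col_double(),
    y_um = readr::col_double()))
  stopifnot(all(c("cell_id", "x_um", "y_um") %in% names(out)))
  out
}

#' @rdname centers_io
#' @export
write_centers <- function(centers, path) {
  readr::write_csv(centers[, c("cell_id", "x_um", "y_um")], path)
  invisible(path)
}
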