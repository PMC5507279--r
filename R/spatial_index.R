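#' Uniform-grid spatial index for range queries on the torus
#'
#' Bins canonical positions into a uniform grid with cell edges at least as
#' long as the intended query radius, so that a 3 x 3 cell neighborhood is
#' guaranteed to cover any radius-`r` disc. A range query then returns exactly
#' the set an all-pairs scan would (the brute-force equivalence is asserted in
#' the test suite).
#'
#' @param points n x 2 matrix of canonical positions.
#' @param geom an [rp_geometry()].
#' @param cell_size cell edge length; must be at least the largest radius
#'   later passed to [neighbors_within()]. Defaults to 1 (the collision
#'   distance of two radius-0.5 molecules).
#' @return an object of class `rp_spatial_index`.
#' @export
spatial_index <- function(points, geom, cell_size = 1) {
  pts <- as_xy(points)
  stopifnot(cell_size > 0)
  if (nrow(pts) > 0 &&
      (any(pts[, 1L] < 0) || any(pts[, 1L] >= geom$width) ||
       any(pts[, 2L] < 0) || any(pts[, 2L] >= geom$height)))
    stop("positions must be canonical (wrapped) before indexing")
  gx <- max(1L, floor(geom$width / cell_size))
  gy <- max(1L, floor(geom$height / cell_size))
  csx <- geom$width / gx
  csy <- geom$height / gy
  ix <- pmin(gx - 1L, floor(pts[, 1L] / csx))
  iy <- pmin(gy - 1L, floor(pts[, 2L] / csy))
  cell <- iy * gx + ix + 1L
  structure(list(points = pts, geom = geom, cell_size = cell_size,
                 gx = gx, gy = gy, csx = csx, csy = csy,
                 bins = split(seq_len(nrow(pts)), factor(cell, levels = seq_len(gx * gy)))),
            class = "rp_spatial_index")
}

#' Range query against a spatial index
#'
#' All indexed points whose center-to-center torus distance to point `i` is
#' strictly below `radius`, excluding `i` itself. Strict inequality matches
#' the overlap rule of the simulator: ties at exactly the collision distance
#' do not react.
#'
#' @param index an [spatial_index()].
#' @param i index (row number) of the query point.
#' @param radius query radius; must not exceed the index cell size.
#' @return integer vector of neighbor row indices (sorted).
#' @export
neighbors_within <- function(index, i, radius) {
  stopifnot(inherits(index, "rp_spatial_index"), radius > 0)
  if (radius > index$cell_size + 1e-12)
    stop("query radius exceeds the index cell size; rebuild with a larger cell")
  pts <- index$points
  stopifnot(i >= 1, i <= nrow(pts))
  p <- pts[i, , drop = FALSE]
  ix0 <- min(index$gx - 1L, floor(p[1L] / index$csx))
  iy0 <- min(index$gy - 1L, floor(p[2L] / index$csy))
  cx <- unique((ix0 + (-1L:1L)) %% index$gx)
  cy <- unique((iy0 + (-1L:1L)) %% index$gy)
  cells <- as.vector(outer(cx, cy, function(x, y) y * index$gx + x + 1L))
  cand <- unlist(index$bins[cells], use.names = FALSE)
  cand <- cand[cand != i]
  if (length(cand) == 0L) return(integer(0))
  d <- torus_distance(pts[cand, , drop = FALSE],
                      pts[rep(i, length(cand)), , drop = FALSE], index$geom)
  sort(cand[d < radius])
}
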