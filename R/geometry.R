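#' Toroidal arena geometry
#'
#' The simulation arena is a 2D torus (periodic in both axes), chosen so that
#' no edge effects perturb the spatial dynamics. One length unit corresponds
#' to one cell side of the source lattice model, so published rate constants
#' transfer without rescaling.
#'
#' @param width arena width in length units (> 0).
#' @param height arena height in length units; defaults to `width` (square
#'   arena).
#' @return an object of class `rp_geometry` with fields `width` and `height`.
#' @examples
#' geom <- rp_geometry(10)
#' wrap_position(c(10.5, -0.5), geom)
#' @export
rp_geometry <- function(width, height = width) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width),
            width > 0, is.numeric(height), length(height) == 1L,
            is.finite(height), height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "rp_geometry")
}

#' @export
print.rp_geometry <- function(x, ...) {
  cat(sprintf("<rp_geometry> %g x %g torus\n", x$width, x$height))
  invisible(x)
}

# coerce a point (length-2 vector) or n x 2 matrix to a matrix
as_xy <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2L)
    storage.mode(p) <- "double"
    p
  } else {
    stopifnot(is.numeric(p), length(p) == 2L)
    matrix(as.numeric(p), ncol = 2L)
  }
}

#' Wrap a position onto the canonical torus domain
#'
#' Maps arbitrary finite coordinates to the half-open fundamental domain
#' `[0, width) x [0, height)`.
#'
#' @param p a length-2 numeric `c(x, y)` or an n x 2 matrix of positions.
#' @param geom an [rp_geometry()].
#' @return wrapped position(s), same shape as `p`.
#' @export
wrap_position <- function(p, geom) {
  xy <- as_xy(p)
  if (any(!is.finite(xy))) stop("invalid position: coordinates must be finite")
  W <- geom$width
  H <- geom$height
  x <- xy[, 1L] %% W
  y <- xy[, 2L] %% H
  # floating-point guard: x %% W can return W for tiny negative x
  x[x >= W] <- 0
  y[y >= H] <- 0
  out <- cbind(x = x, y = y)
  if (is.matrix(p) || is.data.frame(p)) out else out[1L, ]
}

#' Minimal-image distance on the torus
#'
#' Euclidean distance along the shortest wrapped displacement. Symmetric,
#' zero only for identical points, and bounded by
#' `sqrt((W/2)^2 + (H/2)^2)`.
#'
#' @param p,q canonical positions (length-2 vectors or n x 2 matrices).
#' @inheritParams wrap_position
#' @return numeric distance(s).
#' @export
torus_distance <- function(p, q, geom) {
  a <- as_xy(p)
  b <- as_xy(q)
  dx <- abs(a[, 1L] - b[, 1L])
  dx <- pmin(dx, geom$width - dx)
  dy <- abs(a[, 2L] - b[, 2L])
  dy <- pmin(dy, geom$height - dy)
  sqrt(dx * dx + dy * dy)
}

#' Midpoint along the minimal-image segment
#'
#' Returns the point halfway along the shortest wrapped segment from `p` to
#' `q`, wrapped onto the canonical domain. Used to place a newly formed
#' complex between its two colliding members. Antipodal inputs (displacement
#' of exactly half the torus on an axis) have no unique midpoint and raise an
#' error.
#'
#' @inheritParams torus_distance
#' @return midpoint position(s), same shape as `p`.
#' @export
torus_midpoint <- function(p, q, geom) {
  a <- as_xy(p)
  b <- as_xy(q)
  W <- geom$width
  H <- geom$height
  rx <- (b[, 1L] - a[, 1L]) %% W
  ry <- (b[, 2L] - a[, 2L]) %% H
  if (any(rx == W / 2) || any(ry == H / 2))
    stop("ambiguous midpoint: points are antipodal on the torus")
  dx <- ifelse(rx > W / 2, rx - W, rx)
  dy <- ifelse(ry > H / 2, ry - H, ry)
  out <- wrap_position(cbind(a[, 1L] + dx / 2, a[, 2L] + dy / 2), geom)
  if (is.matrix(p) || is.data.frame(p)) out else out[1L, ]
}
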