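#' Render a world state as a raster frame
#'
#' Draws every free molecule as a filled disc of its physical radius and
#' every complex as two overlapping discs at its position, on a black
#' background. Replicases render in blue, parasites in red; brightness
#' encodes the chosen attribute (darkest at 0, brightest at 1). Rendering is
#' deterministic: the same state and style always produce the same pixels.
#'
#' @param state an [rp_world()].
#' @param file optional path; when given the frame is written as PNG.
#' @param scale pixels per length unit.
#' @param attribute which attribute drives brightness: `"a"` or `"l"`.
#' @param radius disc radius in length units (defaults to 0.5).
#' @return the image as a height x width x 3 array in `[0, 1]`, invisibly.
#' @export
render_frame <- function(state, file = NULL, scale = 2,
                         attribute = c("a", "l"), radius = 0.5) {
  stopifnot(inherits(state, "rp_world"), scale > 0)
  attribute <- match.arg(attribute)
  g <- state$geometry
  wpx <- max(1L, as.integer(round(g$width * scale)))
  hpx <- max(1L, as.integer(round(g$height * scale)))
  img <- array(0, dim = c(hpx, wpx, 3L))

  shade <- function(species, value) {
    b <- 0.25 + 0.75 * value
    if (species == "replicase") c(0.1 * b, 0.35 * b, b) else c(b, 0.15 * b, 0.1 * b)
  }
  paint <- function(img, cx, cy, species, value) {
    col <- shade(species, value)
    px <- floor((cx - radius) * scale):ceiling((cx + radius) * scale)
    py <- floor((cy - radius) * scale):ceiling((cy + radius) * scale)
    # pixel centers in world coordinates (unwrapped)
    xc <- (px + 0.5) / scale
    yc <- (py + 0.5) / scale
    inside <- outer((yc - cy)^2, (xc - cx)^2, `+`) <= radius^2
    ix <- px %% wpx + 1L
    iy <- py %% hpx + 1L
    for (k in 1:3) {
      plane <- img[, , k]
      sub <- plane[iy, ix, drop = FALSE]
      sub[inside] <- pmax(sub[inside], col[k])
      plane[iy, ix] <- sub
      img[, , k] <- plane
    }
    img
  }

  m <- state$molecules
  for (i in seq_len(nrow(m)))
    img <- paint(img, m$x[i], m$y[i], m$species[i],
                 if (attribute == "a") m$a[i] else m$l[i])
  cx <- state$complexes
  for (i in seq_len(nrow(cx))) {
    va <- if (attribute == "a") cx$cat_a[i] else cx$cat_l[i]
    vb <- if (attribute == "a") cx$tmpl_a[i] else cx$tmpl_l[i]
    img <- paint(img, cx$x[i] - radius / 2, cx$y[i], cx$cat_species[i], va)
    img <- paint(img, cx$x[i] + radius / 2, cx$y[i], cx$tmpl_species[i], vb)
  }
  if (!is.null(file)) png::writePNG(img, target = file)
  invisible(img)
}
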