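#' Spherocylinder cell geometry
#'
#' Rod-shaped bacteria such as *E. coli* are well approximated by a
#' spherocylinder: a cylinder of radius `radius` capped by two hemispheres.
#' The cell long axis is the x axis and the origin is at the cell center, so
#' the cylindrical section spans `[-(L/2 - r), +(L/2 - r)]` in x.
#'
#' @param total_length Pole-to-pole cell length in micrometers.
#' @param radius Cell radius in micrometers.
#'
#' @return An object of class `cell_geometry` with fields `total_length`,
#'   `radius` and `half_cyl` (half-length of the cylindrical section).
#' @examples
#' geom <- cell_geometry(3.0, 0.5)
#' cell_volume(geom)
#' @export
cell_geometry <- function(total_length, radius) {
  stopifnot(is.numeric(total_length), is.numeric(radius),
            length(total_length) == 1L, length(radius) == 1L)
  if (!is.finite(radius) || radius <= 0)
    stop("cell radius must be positive", call. = FALSE)
  if (!is.finite(total_length) || total_length < 2 * radius)
    stop("cell length must be at least twice the radius (L >= 2r)",
         call. = FALSE)
  structure(
    list(total_length = total_length, radius = radius,
         half_cyl = total_length / 2 - radius),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("spherocylinder cell: L = %.3g um, r = %.3g um, V = %.4g fL\n",
              x$total_length, x$radius, cell_volume(x)))
  invisible(x)
}

#' Spherocylinder cell volume
#'
#' Volume of a cylinder with two hemispherical caps,
#' \eqn{V = \pi r^2 (L - 2r) + \frac{4}{3}\pi r^3}, in femtoliters
#' (1 um^3 = 1 fL).
#'
#' @param geom A [cell_geometry()] object.
#' @return Volume in fL.
#' @export
cell_volume <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  r <- geom$radius
  pi * r^2 * (geom$total_length - 2 * r) + (4 / 3) * pi * r^3
}

#' Test whether points lie inside a spherocylinder
#'
#' A point is inside when its distance to the axial segment of the cylinder
#' is at most the radius (optionally dilated by `tol`, e.g. to allow for
#' localization noise).
#'
#' @param geom A [cell_geometry()] object.
#' @param x,y,z Coordinates in micrometers (`z` defaults to 0 for
#'   2D projected positions).
#' @param tol Dilation of the boundary in micrometers.
#' @return Logical vector.
#' @export
in_cell <- function(geom, x, y, z = 0, tol = 0) {
  stopifnot(inherits(geom, "cell_geometry"))
  h <- geom$half_cyl
  ax <- pmax(abs(x) - h, 0)
  sqrt(ax^2 + y^2 + z^2) <= geom$radius + tol
}

#' Uniform random points in a spherocylinder
#'
#' Samples points uniformly in the cell volume by rejection from the
#' bounding box. Used for the random-site spatial null and to place
#' molecules in the trajectory simulator.
#'
#' @param geom A [cell_geometry()] object.
#' @param n Number of points (`n = 0` gives an empty matrix).
#' @param seed Integer seed; required so that spatial nulls are reproducible.
#' @return An `n x 3` numeric matrix with columns `x`, `y`, `z` (um).
#' @export
sample_points <- function(geom, n, seed) {
  stopifnot(inherits(geom, "cell_geometry"),
            is.numeric(n), length(n) == 1L, n >= 0)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  out <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0L) return(out)
  hx <- geom$total_length / 2
  r <- geom$radius
  got <- 0L
  acc <- vector("list", 0L)
  # acceptance ratio is V_cell / V_box >= pi/6, so a few rounds suffice
  while (got < n) {
    m <- max(64L, ceiling((n - got) * 2.2))
    x <- runif(m, -hx, hx)
    y <- runif(m, -r, r)
    z <- runif(m, -r, r)
    keep <- in_cell(geom, x, y, z)
    if (any(keep)) {
      acc[[length(acc) + 1L]] <- cbind(x = x[keep], y = y[keep], z = z[keep])
      got <- got + sum(keep)
    }
  }
  pts <- do.call(rbind, acc)[seq_len(n), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

# Mirror-reflect points into the spherocylinder.  Points outside are
# reflected across the nearest surface point q: p' = 2q - p.  Iterated a few
# times for the (rare) step that remains outside; finally clamped onto the
# surface.  Operates on an n x 3 matrix in place-style and returns it.
reflect_into_cell <- function(geom, pts) {
  r <- geom$radius
  h <- geom$half_cyl
  for (iter in 1:6) {
    cx <- pmin(pmax(pts[, 1], -h), h)
    dx <- pts[, 1] - cx
    d <- sqrt(dx^2 + pts[, 2]^2 + pts[, 3]^2)
    out <- d > r
    if (!any(out)) return(pts)
    dd <- d[out]
    dd[dd == 0] <- .Machine$double.eps
    # nearest surface point along the radial direction from the axis segment
    scale <- r / dd
    qx <- cx[out] + dx[out] * scale
    qy <- pts[out, 2] * scale
    qz <- pts[out, 3] * scale
    pts[out, 1] <- 2 * qx - pts[out, 1]
    pts[out, 2] <- 2 * qy - pts[out, 2]
    pts[out, 3] <- 2 * qz - pts[out, 3]
  }
  # clamp any stragglers onto the surface
  cx <- pmin(pmax(pts[, 1], -h), h)
  dx <- pts[, 1] - cx
  d <- sqrt(dx^2 + pts[, 2]^2 + pts[, 3]^2)
  out <- d > r
  if (any(out)) {
    scale <- r / d[out]
    pts[out, 1] <- cx[out] + dx[out] * scale
    pts[out, 2] <- pts[out, 2] * scale
    pts[out, 3] <- pts[out, 3] * scale
  }
  pts
}
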