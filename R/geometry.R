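#' Field-of-view geometry from camera parameters
#'
#' Builds a rectangular field of view (FOV) centered at the origin from the
#' camera chip dimensions and the physical pixel size. All geometry in this
#' package is continuous, in micrometres; pixels are metadata that only enter
#' when rendering or reading images.
#'
#' @param n_pixels_x,n_pixels_y Number of pixels along x and y (positive
#'   integers).
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @return An object of class `"fov"`: a list with `width`, `height` (um),
#'   `pixel_size` (um/px) and the pixel counts. The FOV spans
#'   `[-width/2, width/2] x [-height/2, height/2]`.
#' @examples
#' fov_from_camera(1024, 1024, 0.2167)  # ~221.9 um square
#' @seealso [fov_default()] for the 1024 x 1024 px, 216.7 nm/px camera used
#'   throughout, [disk_rect_overlap_fraction()].
#' @export
fov_from_camera <- function(n_pixels_x, n_pixels_y, pixel_size) {
  if (!is.numeric(n_pixels_x) || length(n_pixels_x) != 1L || n_pixels_x <= 0 ||
      !is.numeric(n_pixels_y) || length(n_pixels_y) != 1L || n_pixels_y <= 0 ||
      !is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("fov_from_camera(): all arguments must be positive scalars",
         call. = FALSE)
  }
  structure(list(
    n_pixels_x = as.integer(n_pixels_x),
    n_pixels_y = as.integer(n_pixels_y),
    pixel_size = pixel_size,
    width  = n_pixels_x * pixel_size,
    height = n_pixels_y * pixel_size
  ), class = "fov")
}

#' Default camera field of view
#'
#' The 1024 x 1024 pixel field at 216.7 nm/pixel (221.9 um square) used as
#' the reference imaging geometry.
#' @return An `"fov"` object.
#' @export
fov_default <- function() fov_from_camera(1024L, 1024L, 0.2167)

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("Field of view: %d x %d px at %.4f um/px (%.4f x %.4f um)\n",
              x$n_pixels_x, x$n_pixels_y, x$pixel_size, x$width, x$height))
  invisible(x)
}

#' Circular colony footprint
#'
#' @param x,y Center coordinates in micrometres (FOV-centered frame).
#' @param radius Disk radius in micrometres (>= 0).
#' @return An object of class `"disk"`.
#' @export
disk <- function(x = 0, y = 0, radius = 7.5) {
  if (radius < 0) stop("disk(): radius must be >= 0", call. = FALSE)
  structure(list(center = c(x = x, y = y), radius = radius), class = "disk")
}

# Exact area of {(X,Y): X^2+Y^2 <= r^2, offset by (cx,cy)} intersected with
# the rectangle [x1,x2] x [y1,y2]. Piecewise closed form: 1-D integration of
# the clipped chord length, split at the abscissae where the circle crosses
# y = y1 or y = y2, using the antiderivative of sqrt(r^2 - x^2).
circle_rect_area <- function(cx, cy, r, x1, x2, y1, y2) {
  if (r <= 0) return(0)
  x1 <- x1 - cx; x2 <- x2 - cx; y1 <- y1 - cy; y2 <- y2 - cy
  lo <- max(x1, -r); hi <- min(x2, r)
  if (lo >= hi || y1 >= r || y2 <= -r) return(0)
  G <- function(x) {
    x <- pmin(pmax(x, -r), r)
    0.5 * (x * sqrt(pmax(r * r - x * x, 0)) + r * r * asin(x / r))
  }
  brk <- c(lo, hi)
  for (yy in c(y1, y2)) {
    if (abs(yy) < r) {
      xb <- sqrt(r * r - yy * yy)
      brk <- c(brk, -xb, xb)
    }
  }
  brk <- sort(unique(pmin(pmax(brk, lo), hi)))
  area <- 0
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    if (b - a <= 0) next
    m <- 0.5 * (a + b)
    cm <- sqrt(max(r * r - m * m, 0))
    top <- min(y2, cm)
    bot <- max(y1, -cm)
    if (top <= bot) next
    ti <- if (y2 < cm) y2 * (b - a) else G(b) - G(a)
    bi <- if (y1 > -cm) y1 * (b - a) else -(G(b) - G(a))
    area <- area + (ti - bi)
  }
  area
}

#' Fraction of a disk inside the field of view
#'
#' Exact (closed-form) area of the intersection of a circular colony
#' footprint with the rectangular FOV, divided by the disk area. This is the
#' per-frame "capture fraction" used to score whether a colony's lineage is
#' still being recorded. A zero-radius disk is treated as a point: the
#' fraction is 1 inside the FOV and 0 outside.
#'
#' @param d A [disk()].
#' @param fov An [fov_from_camera()] object.
#' @return A fraction in `[0, 1]`, accurate to better than 1e-6 absolute
#'   (limited only by floating point; the decomposition is exact).
#' @examples
#' f <- fov_default()
#' disk_rect_overlap_fraction(disk(0, 0, 50), f)    # 1: fully inside
#' disk_rect_overlap_fraction(disk(500, 0, 7.5), f) # 0: disjoint
#' @export
disk_rect_overlap_fraction <- function(d, fov) {
  stopifnot(inherits(d, "disk"), inherits(fov, "fov"))
  capture_fraction_xyr(d$center[["x"]], d$center[["y"]], d$radius, fov)
}

# Area of the disk (center 0, radius r) with X >= t, vectorized over (t, r).
# The clamped form is exact for all t: 0 for t >= r, pi r^2 for t <= -r.
disk_halfplane_area <- function(t, r) {
  r * r * acos(pmin(pmax(t / r, -1), 1)) - t * sqrt(pmax(r * r - t * t, 0))
}

# Area of the disk (center 0, radius r) within the quadrant {X >= a, Y >= b},
# vectorized. Derivation: Q = int_{lo}^{r} [c(x) - clamp(b, -c(x), c(x))] dx
# with c(x) = sqrt(r^2 - x^2); the clamp splits at |x| = sqrt(r^2 - b^2) and
# every piece has the standard circular antiderivative.
disk_quadrant_area <- function(a, b, r) {
  G <- function(x) {
    x <- pmin(pmax(x, -r), r)
    0.5 * (x * sqrt(pmax(r * r - x * x, 0)) + r * r * asin(pmin(pmax(x / r, -1), 1)))
  }
  lo <- pmin(pmax(a, -r), r)
  xb <- sqrt(pmax(r * r - b * b, 0))
  xb[abs(b) >= r] <- 0
  mid <- b * pmax(0, xb - pmax(lo, -xb))
  left <- G(-xb) - G(pmin(lo, -xb))
  right <- G(r) - G(pmax(lo, xb))
  full <- G(r) - G(lo)
  pmax(0, full - (mid + sign(b) * (left + right)))
}

#' Vectorized capture fractions for disk centers and radii
#'
#' Same quantity as [disk_rect_overlap_fraction()] for vectors of centers and
#' radii, via the closed-form inclusion-exclusion
#' `area = pi r^2 - sum(4 half-plane caps) + sum(4 corner quadrants)`
#' (opposite half-planes outside a rectangle never intersect, so the
#' expansion terminates at the corner terms).
#'
#' @param x,y,r Numeric vectors (recycled to common length): disk centers and
#'   radii in micrometres.
#' @param fov An `"fov"` object.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
capture_fraction_xyr <- function(x, y, r, fov) {
  n <- max(length(x), length(y), length(r))
  x <- rep_len(x, n); y <- rep_len(y, n); r <- rep_len(r, n)
  hw <- fov$width / 2; hh <- fov$height / 2
  ax <- abs(x); ay <- abs(y)
  f <- numeric(n)

  pt <- r == 0
  if (any(pt)) f[pt] <- as.numeric(ax[pt] <= hw & ay[pt] <= hh)

  inside <- !pt & (ax <= hw - r) & (ay <= hh - r)
  f[inside] <- 1

  dx <- pmax(ax - hw, 0); dy <- pmax(ay - hh, 0)
  disjoint <- !pt & (dx * dx + dy * dy >= r * r)

  rest <- which(!pt & !inside & !disjoint)
  if (length(rest)) {
    # rectangle edges in disk-centered coordinates (symmetric in |x|, |y|)
    xr <- hw - ax[rest]; xl <- hw + ax[rest]
    yt <- hh - ay[rest]; yb <- hh + ay[rest]
    rr <- r[rest]
    area <- pi * rr^2 -
      (disk_halfplane_area(xr, rr) + disk_halfplane_area(xl, rr) +
       disk_halfplane_area(yt, rr) + disk_halfplane_area(yb, rr)) +
      (disk_quadrant_area(xr, yt, rr) + disk_quadrant_area(xr, yb, rr) +
       disk_quadrant_area(xl, yt, rr) + disk_quadrant_area(xl, yb, rr))
    f[rest] <- area / (pi * rr^2)
  }
  pmin(pmax(f, 0), 1)
}
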