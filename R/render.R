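# Synthetic fluorescence-movie generator: renders simulated colonies of
# nuclear-label spots into image stacks with known ground-truth lineages.
#
# Image convention: a frame is a numeric matrix with [row, col] = [y, x];
# pixel (i, j) has its center at x = (j - 0.5 - nx/2) * pixel_size,
# y = (i - 0.5 - ny/2) * pixel_size in the FOV-centered um frame.

#' Rendering configuration for synthetic movies
#'
#' @param psf_sigma Gaussian spot sigma in um (nucleus-scale blob).
#' @param intensity_median Median integrated spot brightness (counts) of a
#'   founding cell. Per-cell brightness is drawn once at birth from a
#'   log-normal and is fixed across frames.
#' @param intensity_gsd Geometric SD of the founder brightness log-normal
#'   (the population heterogeneity that helps tracking).
#' @param division_jitter_gsd At division each daughter receives half the
#'   mother's brightness times an independent log-normal jitter with this
#'   geometric SD (label content splits between daughters).
#' @param illumination Length-6 coefficient vector `(c0, cx, cy, cxx, cyy,
#'   cxy)` of the multiplicative paraboloid bias field
#'   `c0 + cx*x + cy*y + cxx*x^2 + cyy*y^2 + cxy*x*y` evaluated in
#'   FOV-centered um coordinates. The default peaks slightly off-center and
#'   falls ~20% toward the corners.
#' @param background Uniform background level in counts (before the
#'   illumination bias).
#' @param noise `"poisson"` (shot-like, default) or `"gaussian"`.
#' @param noise_sd SD of the Gaussian noise (ignored for Poisson).
#' @param bit_depth Output bit depth; rendered values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @return A `"render_config"` list.
#' @export
render_config <- function(psf_sigma = 3,
                          intensity_median = 4e5,
                          intensity_gsd = 1.8,
                          division_jitter_gsd = 1.1,
                          illumination = c(1.09625, 2.4e-4, -1.8e-4,
                                           -6e-6, -6e-6, 0),
                          background = 100,
                          noise = c("poisson", "gaussian"),
                          noise_sd = 10,
                          bit_depth = 16L) {
  noise <- match.arg(noise)
  if (psf_sigma <= 0 || intensity_median <= 0 || intensity_gsd < 1 ||
      division_jitter_gsd < 1 || background < 0) {
    stop("render_config(): invalid parameter (need psf_sigma > 0, ",
         "positive intensities, GSDs >= 1, background >= 0)", call. = FALSE)
  }
  if (length(illumination) != 6L) {
    stop("render_config(): illumination must have 6 coefficients",
         call. = FALSE)
  }
  structure(list(psf_sigma = psf_sigma,
                 intensity_median = intensity_median,
                 intensity_gsd = intensity_gsd,
                 division_jitter_gsd = division_jitter_gsd,
                 illumination = as.numeric(illumination),
                 background = background, noise = noise,
                 noise_sd = noise_sd, bit_depth = as.integer(bit_depth)),
            class = "render_config")
}

#' Evaluate a paraboloid surface on the pixel grid of a field of view
#'
#' @param coef Length-6 coefficients `(c0, cx, cy, cxx, cyy, cxy)` in
#'   FOV-centered um coordinates.
#' @param fov An `"fov"` object.
#' @return Matrix of surface values, `[row, col] = [y, x]`.
#' @export
paraboloid_surface <- function(coef, fov) {
  xs <- pixel_centers(fov$n_pixels_x, fov$pixel_size)
  ys <- pixel_centers(fov$n_pixels_y, fov$pixel_size)
  m <- matrix(coef[1] + coef[3] * ys + coef[5] * ys^2,
              fov$n_pixels_y, fov$n_pixels_x) +
    matrix(coef[2] * xs + coef[4] * xs^2,
           fov$n_pixels_y, fov$n_pixels_x, byrow = TRUE)
  if (coef[6] != 0) m <- m + coef[6] * outer(ys, xs)
  m
}

# um coordinates of 1-based pixel centers along one axis
pixel_centers <- function(n, pixel_size) {
  (seq_len(n) - 0.5 - n / 2) * pixel_size
}

# um -> 1-based pixel coordinate (continuous)
um_to_px <- function(u, n, pixel_size) u / pixel_size + n / 2 + 0.5

#' Compact circular placement of cells in a colony
#'
#' Places `n` cells on a jittered hexagonal lattice, filling positions
#' closest to the colony center first (random overall orientation), so the
#' colony is compact and approximately circular with non-overlapping cells.
#'
#' @param n Number of cells (>= 1).
#' @param center Colony center `(x, y)` in um.
#' @param r1 Single-cell radius in um.
#' @return An `n x 2` matrix of positions (um). Pairwise distances are at
#'   least `2 * r1 * 0.9` and the enclosing radius is close to
#'   `r1 * sqrt(n)`. Uses the current RNG state (seed upstream for
#'   determinism).
#' @export
place_cells_in_colony <- function(n, center = c(0, 0), r1 = 7.5) {
  if (n < 1) stop("place_cells_in_colony(): n must be >= 1", call. = FALSE)
  if (n == 1L) return(matrix(center, 1, 2, dimnames = list(NULL, c("x", "y"))))
  d <- 2 * r1
  m <- ceiling(1.5 * sqrt(n)) + 2
  ij <- expand.grid(i = -m:m, j = -m:m)
  px <- d * (ij$i + ij$j / 2)
  py <- d * (ij$j * sqrt(3) / 2)
  r2 <- px^2 + py^2
  ord <- order(r2, atan2(py, px))
  pts <- cbind(px[ord], py[ord])[seq_len(n), , drop = FALSE]
  th <- stats::runif(1, 0, 2 * pi)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- pts %*% rot
  pts <- pts + matrix(stats::runif(2 * n, -0.05 * r1, 0.05 * r1), n, 2)
  pts <- sweep(pts, 2, center, "+")
  colnames(pts) <- c("x", "y")
  pts
}

# Soft-disk relaxation of cell offsets after divisions: push overlapping
# pairs apart to a minimum separation and clamp the colony to a compact
# enclosing radius. Deterministic given the input positions.
relax_positions <- function(P, r1, min_sep = 2 * r1 * 0.95,
                            max_iter = 80L) {
  n <- nrow(P)
  if (n < 2L) return(P)
  rmax <- max(1.05 * r1 * sqrt(n), r1)
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    D <- as.matrix(stats::dist(P))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- D[i, j]
        if (dij < min_sep) {
          dir <- if (dij > 1e-9) (P[j, ] - P[i, ]) / dij else c(1, 0)
          push <- (min_sep - dij) / 2
          P[i, ] <- P[i, ] - dir * push
          P[j, ] <- P[j, ] + dir * push
          moved <- TRUE
        }
      }
    }
    rad <- sqrt(rowSums(P^2))
    out <- rad > rmax
    if (any(out)) {
      P[out, ] <- P[out, , drop = FALSE] * (rmax / rad[out])
      moved <- TRUE
    }
    if (!moved) break
  }
  P
}

#' Render one fluorescence frame
#'
#' Each cell contributes a Gaussian spot whose pixel sum equals its
#' brightness; the whole scene sits on a uniform background, is modulated by
#' the multiplicative paraboloid illumination field, degraded by noise, and
#' clipped to the bit depth. Cells outside the FOV simply fall off the edge
#' (that loss is the phenomenon under study).
#'
#' @param cells Data frame with `x`, `y` (um, FOV-centered) and `brightness`.
#'   May have zero rows.
#' @param fov An `"fov"` object.
#' @param config A [render_config()].
#' @param noise Apply the configured noise (set `FALSE` for noise-free
#'   reference frames).
#' @return Numeric matrix `[y, x]`; attribute `clip_fraction` reports the
#'   fraction of saturated pixels.
#' @export
render_frame <- function(cells, fov, config = render_config(),
                         noise = TRUE) {
  ny <- fov$n_pixels_y; nx <- fov$n_pixels_x; ps <- fov$pixel_size
  img <- matrix(config$background, ny, nx)
  if (!is.null(cells) && nrow(cells) > 0L) {
    sig <- config$psf_sigma / ps
    hw <- ceiling(4 * sig)
    for (k in seq_len(nrow(cells))) {
      cx <- um_to_px(cells$x[k], nx, ps)
      cy <- um_to_px(cells$y[k], ny, ps)
      j1 <- max(1L, floor(cx - hw)); j2 <- min(nx, ceiling(cx + hw))
      i1 <- max(1L, floor(cy - hw)); i2 <- min(ny, ceiling(cy + hw))
      if (j1 > j2 || i1 > i2) next
      gx <- stats::dnorm(j1:j2, cx, sig)
      gy <- stats::dnorm(i1:i2, cy, sig)
      img[i1:i2, j1:j2] <- img[i1:i2, j1:j2] +
        cells$brightness[k] * (gy %o% gx)
    }
  }
  img <- img * paraboloid_surface(config$illumination, fov)
  if (noise) {
    if (config$noise == "poisson") {
      img <- matrix(stats::rpois(length(img), pmax(img, 0)), ny, nx)
    } else {
      img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                          ny, nx)
    }
  }
  top <- 2^config$bit_depth - 1
  clip <- mean(img > top | img < 0)
  img <- pmin(pmax(img, 0), top)
  attr(img, "clip_fraction") <- clip
  img
}

#' Generate a synthetic movie with ground-truth lineage
#'
#' Couples the colony simulator to the renderer: the colony center performs
#' the configured random walk while cells divide under the selected growth
#' model. Daughters are placed at the mother's position plus/minus one cell
#' radius in a random direction, after which cell offsets are relaxed to
#' restore compact non-overlapping packing (the colony is otherwise rigid).
#' Each cell's brightness is drawn at birth (log-normal founders; daughters
#' get half the mother's brightness with multiplicative jitter).
#'
#' @param growth,migration,fov Simulation parameter objects.
#' @param duration Movie length in hours.
#' @param config A [render_config()].
#' @param seed Integer seed; the full stack and ground truth are
#'   deterministic given the seed.
#' @return A `"synthetic_movie"`: `frames` (list of matrices), `truth`
#'   (data frame: frame, cell_id, parent_id, x_um, y_um, x_px, y_px,
#'   brightness, in_fov), `divisions` (frame, time_min, parent, child1,
#'   child2), frame `times` (min), colony `center` matrix, and the
#'   parameter objects.
#' @examples
#' mv <- make_movie(duration = 12, fov = fov_from_camera(128, 128, 0.8672),
#'                  seed = 1)
#' length(mv$frames)
#' @export
make_movie <- function(growth = growth_params(),
                       migration = migration_params(),
                       fov = fov_default(),
                       duration = 24,
                       config = render_config(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration < 0) stop("make_movie(): duration must be >= 0", call. = FALSE)
  dur_min <- duration * 60
  fi <- migration$frame_interval
  n_frames <- floor(dur_min / fi + 1e-9) + 1L
  times <- (seq_len(n_frames) - 1L) * fi

  # division event schedule: (time, which cells divide)
  if (growth$mode == "synchronized") {
    epoch <- growth$division_interval * 60
    ev_times <- if (dur_min >= epoch) seq(epoch, dur_min, by = epoch)
                else numeric(0)
  } else {
    ev_times <- if (duration > 0) gillespie_division_times(duration, growth)
                else numeric(0)
  }

  # colony-center walk at frame resolution
  if (n_frames > 1L && migration$step_length > 0) {
    spf <- as.integer(round(fi / migration$step_interval))
    th <- stats::runif(spf * (n_frames - 1L), 0, 2 * pi)
    cen <- cbind(
      c(0, cumsum(.colSums(cos(th), spf, n_frames - 1L) * migration$step_length)),
      c(0, cumsum(.colSums(sin(th), spf, n_frames - 1L) * migration$step_length)))
  } else {
    cen <- matrix(0, n_frames, 2)
  }

  r1 <- growth$r1
  off <- matrix(0, 1, 2)                    # offsets relative to colony center
  id <- 1L; parent <- NA_integer_
  bright <- config$intensity_median *
    exp(stats::rnorm(1, 0, log(config$intensity_gsd)))
  next_id <- 2L
  ev_idx <- 1L
  truth <- vector("list", n_frames)
  divisions <- list()

  for (f in seq_len(n_frames)) {
    # apply divisions scheduled up to (and including) this frame time
    while (ev_idx <= length(ev_times) && ev_times[ev_idx] <= times[f]) {
      tdiv <- ev_times[ev_idx]
      mothers <- if (growth$mode == "synchronized") seq_along(id)
                 else sample.int(length(id), 1L)
      for (mi in mothers) {
        u <- stats::runif(1, 0, 2 * pi)
        dvec <- r1 * c(cos(u), sin(u))
        jit <- exp(stats::rnorm(2, 0, log(config$division_jitter_gsd)))
        kids <- c(next_id, next_id + 1L)
        off <- rbind(off, off[mi, ] + dvec, off[mi, ] - dvec)
        id <- c(id, kids)
        parent <- c(parent, id[mi], id[mi])
        bright <- c(bright, bright[mi] / 2 * jit)
        divisions[[length(divisions) + 1L]] <-
          data.frame(frame = f, time_min = tdiv, parent = id[mi],
                     child1 = kids[1], child2 = kids[2])
        next_id <- next_id + 2L
      }
      keep <- !(seq_along(id) %in% mothers)
      off <- off[keep, , drop = FALSE]
      id <- id[keep]; parent <- parent[keep]; bright <- bright[keep]
      off <- relax_positions(off, r1)
      ev_idx <- ev_idx + 1L
    }
    x <- cen[f, 1] + off[, 1]
    y <- cen[f, 2] + off[, 2]
    truth[[f]] <- data.frame(
      frame = f, cell_id = id, parent_id = parent,
      x_um = x, y_um = y,
      x_px = um_to_px(x, fov$n_pixels_x, fov$pixel_size),
      y_px = um_to_px(y, fov$n_pixels_y, fov$pixel_size),
      brightness = bright,
      in_fov = abs(x) <= fov$width / 2 & abs(y) <= fov$height / 2)
  }
  truth <- do.call(rbind, truth)

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    tf <- truth[truth$frame == f, ]
    frames[[f]] <- render_frame(
      data.frame(x = tf$x_um, y = tf$y_um, brightness = tf$brightness),
      fov, config)
  }

  structure(list(
    frames = frames, truth = truth,
    divisions = if (length(divisions)) do.call(rbind, divisions)
                else data.frame(frame = integer(), time_min = numeric(),
                                parent = integer(), child1 = integer(),
                                child2 = integer()),
    times = times, center = cen, config = config, fov = fov,
    growth = growth, migration = migration, duration = duration,
    seed = seed
  ), class = "synthetic_movie")
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf("Synthetic movie: %d frames (%d x %d px), %d cells at end, %d divisions\n",
              length(x$frames), x$fov$n_pixels_y, x$fov$n_pixels_x,
              sum(x$truth$frame == length(x$frames)), nrow(x$divisions)))
  invisible(x)
}

#' Write a movie to a multi-frame 16-bit TIFF
#'
#' @param movie A `"synthetic_movie"` or a list of numeric frame matrices.
#' @param path Output file.
#' @param bit_depth Bit depth used for scaling (default from the movie's
#'   config, else 16).
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, bit_depth = NULL) {
  frames <- if (inherits(movie, "synthetic_movie")) movie$frames else movie
  if (is.null(bit_depth)) {
    bit_depth <- if (inherits(movie, "synthetic_movie"))
      movie$config$bit_depth else 16L
  }
  top <- 2^bit_depth - 1
  tiff::writeTIFF(lapply(frames, function(f) {
    f <- pmin(pmax(f, 0), top) / top
    attributes(f) <- list(dim = dim(f))
    f
  }), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame TIFF as a list of count matrices
#'
#' @param path TIFF file written by [write_movie_tiff()] (or any grayscale
#'   stack).
#' @param bit_depth Bit depth used to rescale intensities back to counts.
#' @return List of numeric matrices `[y, x]`.
#' @export
read_movie_tiff <- function(path, bit_depth = 16L) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    f * (2^bit_depth - 1)
  })
}
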