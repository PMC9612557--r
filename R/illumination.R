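# Flat-field correction: fit a 2-D quadratic (paraboloid) to background
# pixel intensities and divide the image by it.

#' Correct inhomogeneous illumination by paraboloid normalization
#'
#' Fits the 6-coefficient quadratic surface
#' `c0 + cx*x + cy*y + cxx*x^2 + cyy*y^2 + cxy*x*y` to background (non-cell)
#' pixel intensities by least squares and divides the image by it, so the
#' corrected background is flat at level ~1. If no cell mask is supplied,
#' background pixels are found by a coarse robust threshold
#' (median + 3 * MAD) and the fit is iterated once on the pixels that are
#' background after the first correction.
#'
#' @param img Numeric matrix `[y, x]` of intensities.
#' @param mask Optional logical matrix, `TRUE` for background pixels. If
#'   `NULL`, estimated as described above.
#' @param fov Optional `"fov"`; when given, the surface is parameterized in
#'   FOV-centered um coordinates (so fitted coefficients are directly
#'   comparable to a generator's illumination coefficients times the
#'   background level). Otherwise centered pixel coordinates are used.
#' @param max_points Background pixels are subsampled to at most this many
#'   for the least-squares fit.
#' @return A list: `corrected` (matrix), `coefficients` (length 6),
#'   `surface` (fitted matrix), `background_mask` (logical matrix used in
#'   the final fit).
#' @export
correct_illumination <- function(img, mask = NULL, fov = NULL,
                                 max_points = 20000L) {
  stopifnot(is.matrix(img))
  iterate <- is.null(mask)
  if (is.null(mask)) {
    mask <- img <= stats::median(img) + 3 * stats::mad(img)
  }
  fit1 <- fit_paraboloid(img, mask, fov, max_points)
  if (iterate) {
    corr0 <- img / fit1$surface
    mask <- corr0 <= stats::median(corr0) + 3 * stats::mad(corr0)
    fit1 <- fit_paraboloid(img, mask, fov, max_points)
  }
  list(corrected = img / fit1$surface,
       coefficients = fit1$coefficients,
       surface = fit1$surface,
       background_mask = mask)
}

fit_paraboloid <- function(img, mask, fov = NULL, max_points = 20000L) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(fov)) {
    xs <- seq_len(nx) - (nx + 1) / 2
    ys <- seq_len(ny) - (ny + 1) / 2
  } else {
    xs <- pixel_centers(nx, fov$pixel_size)
    ys <- pixel_centers(ny, fov$pixel_size)
  }
  idx <- which(mask)
  if (length(idx) < 6L) {
    stop("fit_paraboloid(): fewer background pixels than coefficients",
         call. = FALSE)
  }
  if (length(idx) > max_points) {
    idx <- idx[round(seq(1L, length(idx), length.out = max_points))]
  }
  ri <- ((idx - 1L) %% ny) + 1L
  ci <- ((idx - 1L) %/% ny) + 1L
  x <- xs[ci]; y <- ys[ri]
  X <- cbind(1, x, y, x^2, y^2, x * y)
  cf <- stats::lm.fit(X, img[idx])$coefficients
  cf[is.na(cf)] <- 0
  # evaluate fitted surface on the full grid
  surf <- matrix(cf[1] + cf[3] * ys + cf[5] * ys^2, ny, nx) +
    matrix(cf[2] * xs + cf[4] * xs^2, ny, nx, byrow = TRUE)
  if (cf[6] != 0) surf <- surf + cf[6] * outer(ys, xs)
  list(coefficients = unname(cf), surface = surf)
}
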