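# Threshold segmentation of nucleus spots on flat-field-corrected frames.

#' Segment nucleus spots by intensity threshold
#'
#' Thresholds the (corrected) image and extracts connected components of
#' supra-threshold pixels as detections, with intensity-weighted centroids
#' and summed intensities. Two touching nuclei may come out as one merged
#' detection; that is accepted here and handled downstream by the
#' discontinuity heuristics.
#'
#' @param img Numeric matrix `[y, x]`, typically the `corrected` image from
#'   [correct_illumination()] (background ~1).
#' @param threshold Either a numeric cutoff on `img`, `"otsu"` (Otsu's
#'   threshold on the intensity histogram), or `"auto"` (default: the larger
#'   of the Otsu threshold and median + 5 * MAD, which suppresses spurious
#'   components on cell-free frames).
#' @param min_area Discard components smaller than this many pixels.
#' @param background Per-pixel background level subtracted before summing a
#'   component's intensity (so `intensity` estimates the spot's integrated
#'   mass, not mass + area * background). `NULL` (default) uses the image
#'   median -- ~1 on a flat-field-corrected frame. Set 0 for raw sums.
#' @return A data frame of detections: `id`, `x_px`, `y_px` (1-based pixel
#'   coordinates, intensity-weighted), `intensity` (background-subtracted
#'   sum over the component), `area` (px). Zero rows if nothing is found.
#' @export
segment_cells <- function(img, threshold = "auto", min_area = 20L,
                          background = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(background)) background <- stats::median(img)
  thr <- resolve_threshold(img, threshold)
  mask <- img > thr
  empty <- data.frame(id = integer(), x_px = numeric(), y_px = numeric(),
                      intensity = numeric(), area = integer())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  # EBImage images are (x, y); transpose back to [row, col] = [y, x]
  lab <- t(EBImage::imageData(lab))
  idx <- which(lab > 0L)
  li <- lab[idx]
  area <- tabulate(li)
  w <- img[idx]
  ri <- ((idx - 1L) %% nrow(img)) + 1L
  ci <- ((idx - 1L) %/% nrow(img)) + 1L
  wsum <- rowsum(w, li)
  xw <- rowsum(w * ci, li) / wsum
  yw <- rowsum(w * ri, li) / wsum
  mass <- rowsum(pmax(w - background, 0), li)
  keep <- which(area >= min_area)
  if (!length(keep)) return(empty)
  data.frame(id = seq_along(keep),
             x_px = xw[keep, 1], y_px = yw[keep, 1],
             intensity = mass[keep, 1], area = as.integer(area[keep]))
}

resolve_threshold <- function(img, threshold) {
  if (is.numeric(threshold)) return(threshold)
  med <- stats::median(img)
  robust <- med + 5 * stats::mad(img)
  rng <- range(img)
  if (rng[2] <= rng[1]) return(robust)
  ot <- EBImage::otsu(EBImage::Image(t(img)), range = rng)
  switch(threshold,
         otsu = ot,
         auto = max(ot, robust),
         stop("segment_cells(): threshold must be numeric, 'otsu' or 'auto'",
              call. = FALSE))
}
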