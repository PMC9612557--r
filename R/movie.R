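# Single-movie simulation: rigid-colony random walk + growth model, scored
# by the per-frame capture fraction of the colony disk inside the FOV.

# Simulate frame-resolution colony state. Assumes the RNG state is already
# set by the caller. Draw order is fixed (growth first, then walk) so that
# a given seed always yields the same movie.
sim_colony_frames <- function(growth, migration, fov, duration) {
  dur_min <- duration * 60
  fi <- migration$frame_interval
  n_frames <- floor(dur_min / fi + 1e-9) + 1L
  times <- (seq_len(n_frames) - 1L) * fi

  if (growth$mode == "synchronized") {
    counts <- synchronized_cell_count(times, growth)
  } else if (duration > 0) {
    dt <- gillespie_division_times(duration, growth)
    counts <- findInterval(times, dt) + 1
  } else {
    counts <- rep(1, n_frames)
  }

  if (n_frames > 1L && migration$step_length > 0) {
    spf <- as.integer(round(fi / migration$step_interval))
    th <- stats::runif(spf * (n_frames - 1L), 0, 2 * pi)
    L <- migration$step_length
    inc_x <- .colSums(cos(th), spf, n_frames - 1L) * L
    inc_y <- .colSums(sin(th), spf, n_frames - 1L) * L
    x <- c(0, cumsum(inc_x))
    y <- c(0, cumsum(inc_y))
  } else {
    x <- y <- numeric(n_frames)
  }

  list(times = times, n_cells = counts,
       radius = colony_radius_from_count(counts, growth), x = x, y = y)
}

#' Simulate one time-lapse movie of a migrating, growing colony
#'
#' A single cell starts at the center of the field of view. The colony moves
#' as a rigid disk whose center performs an isotropic fixed-step random walk,
#' while its area grows by the selected model (synchronized doubling or
#' continuous-time pure-birth). At every frame the fraction of the colony
#' disk inside the FOV is recorded; a movie's score is the minimum of that
#' trajectory ("throughout" criterion) or its final value.
#'
#' @param growth A [growth_params()] object.
#' @param migration A [migration_params()] object.
#' @param fov An [fov_from_camera()] object.
#' @param duration Recording length in hours (>= 0; 0 gives the single
#'   initial frame).
#' @param seed Optional integer seed; with a seed the result is fully
#'   deterministic.
#' @return A `"movie_result"`: frame `times` (min), `n_cells`, colony
#'   `radius` (um), center `x`, `y` (um), `capture_fraction` per frame, and
#'   the `min_fraction` / `final_fraction` summaries.
#' @examples
#' m <- simulate_movie(duration = 24, seed = 1)
#' m$min_fraction
#' @export
simulate_movie <- function(growth = growth_params(),
                           migration = migration_params(),
                           fov = fov_default(),
                           duration = 96, seed = NULL) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(migration, "migration_params"),
            inherits(fov, "fov"))
  if (duration < 0) {
    stop("simulate_movie(): duration must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  s <- sim_colony_frames(growth, migration, fov, duration)
  frac <- capture_fraction_xyr(s$x, s$y, s$radius, fov)
  structure(list(
    times = s$times, n_cells = s$n_cells, radius = s$radius,
    x = s$x, y = s$y, capture_fraction = frac,
    min_fraction = min(frac), final_fraction = frac[length(frac)],
    seed = seed, growth = growth, migration = migration, fov = fov,
    duration = duration
  ), class = "movie_result")
}

#' @export
print.movie_result <- function(x, ...) {
  cat(sprintf(
    "Simulated movie: %d frames over %.1f hr, %s growth\n",
    length(x$times), x$duration, x$growth$mode))
  cat(sprintf("  final n = %d cells, radius %.1f um\n",
              as.integer(x$n_cells[length(x$n_cells)]),
              x$radius[length(x$radius)]))
  cat(sprintf("  capture fraction: min %.3f, final %.3f\n",
              x$min_fraction, x$final_fraction))
  invisible(x)
}

#' Flatten a movie result to one row per frame
#'
#' @param x A `"movie_result"`.
#' @param row.names,optional Ignored (S3 signature).
#' @param movie_id Identifier repeated on every row.
#' @param ... Unused.
#' @return A data frame with columns `movie_id`, `time_min`, `n_cells`,
#'   `radius_um`, `x_um`, `y_um`, `capture_fraction`.
#' @export
as.data.frame.movie_result <- function(x, row.names = NULL, optional = FALSE,
                                       movie_id = 1L, ...) {
  data.frame(movie_id = movie_id, time_min = x$times, n_cells = x$n_cells,
             radius_um = x$radius, x_um = x$x, y_um = x$y,
             capture_fraction = x$capture_fraction)
}

#' Summarize a movie result as a list (or JSON)
#'
#' @param result A `"movie_result"`.
#' @param path Optional path; when given, the JSON summary is written there.
#' @return A list with the scalar summary of the movie (also JSON-encoded
#'   to `path` when requested).
#' @export
movie_summary <- function(result, path = NULL) {
  out <- list(
    duration_hr = result$duration,
    n_frames = length(result$times),
    growth_mode = result$growth$mode,
    final_n_cells = result$n_cells[length(result$n_cells)],
    final_radius_um = result$radius[length(result$radius)],
    min_fraction = result$min_fraction,
    final_fraction = result$final_fraction,
    seed = result$seed)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Classify a movie against capture thresholds
#'
#' Under the `"throughout"` criterion a movie passes a threshold `theta` when
#' its minimum capture fraction over all frames is at least `theta` (the
#' lineage stayed captured for the whole recording). Under `"final_frame"`
#' only the last frame is scored.
#'
#' @param result A `"movie_result"`, or any list with a `capture_fraction`
#'   vector.
#' @param thresholds Numeric thresholds in `(0, 1]`.
#' @param criterion `"throughout"` (default) or `"final_frame"`.
#' @return Named logical vector, one element per threshold.
#' @examples
#' classify_capture(list(capture_fraction = c(1, 0.95, 0.91)))
#' @export
classify_capture <- function(result, thresholds = c(0.5, 0.9),
                             criterion = c("throughout", "final_frame")) {
  criterion <- match.arg(criterion)
  frac <- result$capture_fraction
  if (is.null(frac) || length(frac) == 0L) {
    stop("classify_capture(): empty capture trajectory", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("classify_capture(): thresholds must lie in (0, 1]", call. = FALSE)
  }
  score <- if (criterion == "throughout") min(frac) else frac[length(frac)]
  stats::setNames(score >= thresholds, paste0("ge_", thresholds))
}
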