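#' Colony growth parameters
#'
#' @param r1 Single-cell (nucleus footprint) radius in micrometres.
#' @param division_interval Cell-cycle length in hours. Under the
#'   synchronized model the whole colony doubles every `division_interval`;
#'   under the Gillespie model it sets the per-division waiting-time scale
#'   `division_interval / n` for a colony of `n` cells.
#' @param mode `"synchronized"` (all cells divide together, colony area
#'   doubles) or `"gillespie"` (continuous-time pure-birth process, colony
#'   area grows by one cell area per division).
#' @return A `"growth_params"` list.
#' @export
growth_params <- function(r1 = 7.5, division_interval = 12,
                          mode = c("synchronized", "gillespie")) {
  mode <- match.arg(mode)
  if (r1 <= 0) stop("growth_params(): r1 must be > 0", call. = FALSE)
  if (division_interval <= 0) {
    stop("growth_params(): division_interval must be > 0", call. = FALSE)
  }
  structure(list(r1 = r1, division_interval = division_interval, mode = mode),
            class = "growth_params")
}

#' Colony migration parameters
#'
#' The colony center performs an isotropic fixed-step random walk: every
#' `step_interval` minutes it moves `speed * step_interval` micrometres in a
#' uniformly random direction. Two step conventions are in use:
#'
#' * `"per-minute"` (default): one 1-um step per simulated minute
#'   (`step_interval = 1`), the literal reading of a cell speed of
#'   1 um/min. Effective diffusivity `speed^2 * step_interval / 4` =
#'   0.25 um^2/min.
#' * `"per-frame"`: one step per 15-min frame with length
#'   `speed * frame_interval` = 15 um, matching a measured mean per-frame
#'   displacement of 15 um (diffusivity 3.75 um^2/min).
#'
#' @param speed Migration speed in um/min.
#' @param step_interval Minutes between random-walk steps; `frame_interval`
#'   must be an integer multiple of it.
#' @param frame_interval Minutes between recorded movie frames.
#' @return A `"migration_params"` list with the derived `step_length` (um).
#' @seealso [migration_convention()]
#' @export
migration_params <- function(speed = 1, step_interval = 1,
                             frame_interval = 15) {
  if (speed < 0 || step_interval <= 0 || frame_interval <= 0) {
    stop("migration_params(): speed must be >= 0 and intervals > 0",
         call. = FALSE)
  }
  k <- frame_interval / step_interval
  if (abs(k - round(k)) > 1e-9) {
    stop("migration_params(): frame_interval must be an integer multiple ",
         "of step_interval", call. = FALSE)
  }
  structure(list(speed = speed, step_interval = step_interval,
                 frame_interval = frame_interval,
                 step_length = speed * step_interval),
            class = "migration_params")
}

#' Migration parameters for a named step convention
#'
#' @param convention `"per-minute"` or `"per-frame"`; see
#'   [migration_params()] for what each means.
#' @param speed Migration speed in um/min.
#' @param frame_interval Minutes between frames.
#' @return A `"migration_params"` object.
#' @export
migration_convention <- function(convention = c("per-minute", "per-frame"),
                                 speed = 1, frame_interval = 15) {
  convention <- match.arg(convention)
  step <- if (convention == "per-minute") 1 else frame_interval
  migration_params(speed = speed, step_interval = step,
                   frame_interval = frame_interval)
}

#' Cell count under the synchronized cell-cycle model
#'
#' All cells divide simultaneously every `division_interval`, so the count
#' doubles at each epoch: `n(t) = 2^floor(t / division_interval)`.
#'
#' @param t_min Time since plating, in minutes (>= 0, vectorized).
#' @param growth A [growth_params()] object.
#' @return Cell counts (numeric; exact powers of two).
#' @export
synchronized_cell_count <- function(t_min, growth = growth_params()) {
  if (any(t_min < 0)) {
    stop("synchronized_cell_count(): t_min must be >= 0", call. = FALSE)
  }
  2^floor(t_min / (growth$division_interval * 60))
}

#' Waiting time to the next division of an n-cell colony
#'
#' The continuous stochastic growth model draws the time to the next division
#' of an `n`-cell colony as `-(division_interval / n) * log(u)` with
#' `u ~ Uniform(0, 1)` -- an exponential with mean `division_interval / n`
#' (a pure-birth / Yule process).
#'
#' @param u Uniform(0,1) variate(s).
#' @param n Current cell count(s).
#' @param growth A [growth_params()] object.
#' @return Waiting time(s) in minutes.
#' @export
gillespie_waiting_time <- function(u, n, growth = growth_params()) {
  -(growth$division_interval * 60 / n) * log(u)
}

#' Division event times of the continuous stochastic growth model
#'
#' Simulates the pure-birth process: starting from one cell, successive
#' waiting times are exponential with mean `division_interval / n` for the
#' current count `n`, and each event adds one cell. Events beyond `duration`
#' are discarded.
#'
#' @param duration Recording length in hours (> 0).
#' @param growth A [growth_params()] object.
#' @return Sorted division times in minutes (possibly empty). The cell count
#'   at time `t` min is `findInterval(t, times) + 1`.
#' @export
gillespie_division_times <- function(duration, growth = growth_params()) {
  if (duration <= 0) {
    stop("gillespie_division_times(): duration must be > 0", call. = FALSE)
  }
  scale_min <- growth$division_interval * 60
  dur_min <- duration * 60
  times <- numeric(0)
  t_cum <- 0
  n <- 1L
  alloc <- 64L
  repeat {
    w <- scale_min * stats::rexp(alloc) / seq.int(n, n + alloc - 1L)
    ct <- t_cum + cumsum(w)
    keep <- ct <= dur_min
    times <- c(times, ct[keep])
    if (!all(keep)) break
    t_cum <- ct[alloc]
    n <- n + alloc
    alloc <- alloc * 2L
  }
  times
}

#' Colony radius from cell count
#'
#' Area additivity: a colony of `n` cells of radius `r1` occupies area
#' `n * pi * r1^2`, hence radius `r1 * sqrt(n)`.
#'
#' @param n_cells Cell count(s).
#' @param growth A [growth_params()] object.
#' @return Colony radius (um).
#' @export
colony_radius_from_count <- function(n_cells, growth = growth_params()) {
  growth$r1 * sqrt(n_cells)
}

#' One step of the isotropic fixed-length random walk
#'
#' @param center Length-2 numeric `(x, y)` in um.
#' @param step_length Step length in um (>= 0).
#' @return New `(x, y)` position; the displacement magnitude is exactly
#'   `step_length`, in a direction uniform on `[0, 2*pi)`.
#' @export
random_walk_step <- function(center, step_length) {
  if (step_length < 0) {
    stop("random_walk_step(): step_length must be >= 0", call. = FALSE)
  }
  theta <- stats::runif(1, 0, 2 * pi)
  c(center[1] + step_length * cos(theta),
    center[2] + step_length * sin(theta))
}
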