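# Batch Monte-Carlo experiments: many independent movies, batch pass
# fractions, and the effective-throughput summary statistics.

#' Deterministic per-movie seed from a root seed
#'
#' Movies in an experiment get independent, order-stable RNG substreams: the
#' seed of movie `i` depends only on the root seed and `i` (a multiplicative
#' hash modulo 2^31 - 1), so enlarging an experiment leaves earlier movies'
#' outcomes unchanged.
#'
#' @param root Root integer seed.
#' @param index Movie index (1-based; vectorized).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_movie_seed <- function(root, index) {
  m <- 2147483647
  s <- ((root %% m) * 69069) %% m
  as.integer((s + (index * 30103) %% m) %% (m - 1) + 1)
}

#' Design of a batch Monte-Carlo capture experiment
#'
#' @param n_batches Number of batches (the printed "+/-" spread is the SD of
#'   per-batch pass fractions).
#' @param batch_size Movies per batch; 100 mirrors a typical number of
#'   programmed stage positions per experiment.
#' @param duration Movie length in hours.
#' @param growth,migration,fov Component parameter objects.
#' @param thresholds Capture thresholds to classify against.
#' @param criterion `"final_frame"` or `"throughout"` (see
#'   [classify_capture()]). The experiment-level defaults -- per-frame step
#'   convention and final-frame scoring -- are the calibrated combination
#'   that comes closest to the reference no-pattern capture percentages; see
#'   the methods vignette for the calibration and its caveats.
#' @param seed Root seed for the experiment.
#' @param movie_cap Refuse designs larger than this many movies.
#' @return An `"experiment_design"` list.
#' @export
experiment_design <- function(n_batches = 1000, batch_size = 100,
                              duration = 96,
                              growth = growth_params(),
                              migration = migration_convention("per-frame"),
                              fov = fov_default(),
                              thresholds = c(0.5, 0.9),
                              criterion = c("final_frame", "throughout"),
                              seed = 1, movie_cap = 2e5) {
  criterion <- match.arg(criterion)
  if (n_batches < 1 || batch_size < 1) {
    stop("experiment_design(): n_batches and batch_size must be >= 1",
         call. = FALSE)
  }
  structure(list(n_batches = as.integer(n_batches),
                 batch_size = as.integer(batch_size),
                 duration = duration, growth = growth,
                 migration = migration, fov = fov,
                 thresholds = sort(thresholds), criterion = criterion,
                 seed = seed, movie_cap = movie_cap),
            class = "experiment_design")
}

# Fast batch core: min and final capture fraction for each seed, without
# retaining full trajectories.
sim_min_final <- function(seeds, growth, migration, fov, duration) {
  n <- length(seeds)
  mins <- finals <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    s <- sim_colony_frames(growth, migration, fov, duration)
    frac <- capture_fraction_xyr(s$x, s$y, s$radius, fov)
    mins[i] <- min(frac)
    finals[i] <- frac[length(frac)]
  }
  list(min = mins, final = finals)
}

#' Run a batch Monte-Carlo capture experiment
#'
#' Simulates `n_batches * batch_size` independent movies (each on its own
#' derived seed), classifies each against the capture thresholds, and
#' summarizes, per threshold, the mean and SD across batches of the
#' within-batch pass fraction.
#'
#' @param design An [experiment_design()].
#' @param progress Print a progress line every 10 batches.
#' @return A `"batch_stats"` object: data frame `stats` with one row per
#'   threshold (`threshold`, `mean_fraction`, `sd_fraction`, `n_pass`,
#'   `n_movies`), the per-batch fraction matrix `batch_fractions`
#'   (batches x thresholds), and the design.
#' @examples
#' d <- experiment_design(n_batches = 2, batch_size = 5, duration = 24,
#'                        seed = 7)
#' run_experiment(d)$stats
#' @export
run_experiment <- function(design, progress = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  n_total <- design$n_batches * design$batch_size
  if (n_total > design$movie_cap) {
    stop(sprintf(paste0(
      "run_experiment(): design asks for %d movies, above the cap of %g; ",
      "raise movie_cap explicitly if this is intended"),
      n_total, design$movie_cap), call. = FALSE)
  }
  thr <- design$thresholds
  use_min <- design$criterion == "throughout"
  batch_frac <- matrix(NA_real_, design$n_batches, length(thr),
                       dimnames = list(NULL, paste0("ge_", thr)))
  n_pass <- numeric(length(thr))
  for (b in seq_len(design$n_batches)) {
    idx <- (b - 1L) * design$batch_size + seq_len(design$batch_size)
    seeds <- derive_movie_seed(design$seed, idx)
    mf <- sim_min_final(seeds, design$growth, design$migration,
                        design$fov, design$duration)
    score <- if (use_min) mf$min else mf$final
    for (k in seq_along(thr)) {
      pass <- score >= thr[k]
      batch_frac[b, k] <- mean(pass)
      n_pass[k] <- n_pass[k] + sum(pass)
    }
    if (progress && b %% 10L == 0L) {
      message(sprintf("batch %d / %d", b, design$n_batches))
    }
  }
  stats_df <- data.frame(
    threshold = thr,
    mean_fraction = colMeans(batch_frac),
    sd_fraction = apply(batch_frac, 2, stats::sd),
    n_pass = n_pass,
    n_movies = n_total,
    row.names = NULL
  )
  structure(list(stats = stats_df, batch_fractions = batch_frac,
                 design = design), class = "batch_stats")
}

#' @export
print.batch_stats <- function(x, ...) {
  d <- x$design
  cat(sprintf("Capture statistics: %d movies (%d batches of %d), %s growth, %s\n",
              d$n_batches * d$batch_size, d$n_batches, d$batch_size,
              d$growth$mode, d$criterion))
  s <- x$stats
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  > %.0f%% capture: %.1f%% +/- %.1f%% of positions\n",
                100 * s$threshold[i], 100 * s$mean_fraction[i],
                100 * s$sd_fraction[i]))
  }
  invisible(x)
}

#' Effective-throughput improvement ratio
#'
#' Ratio of the full-lineage recording rate on a patterned surface to the
#' rate in the unpatterned (free-drift) condition.
#'
#' @param patterned_rate,unpatterned_rate Pass fractions in `[0, 1]`.
#' @return `patterned_rate / unpatterned_rate`.
#' @export
throughput_improvement <- function(patterned_rate, unpatterned_rate) {
  if (unpatterned_rate <= 0) {
    stop(paste0(
      "throughput_improvement(): unpatterned rate is 0 -- the ratio is ",
      "undefined; report a lower bound instead, e.g. patterned_rate * ",
      "total_movies (no simulated movie passed)"), call. = FALSE)
  }
  patterned_rate / unpatterned_rate
}

#' Flatten batch statistics to report rows
#'
#' @param stats A `"batch_stats"` object (or NULL for an empty table).
#' @param label Model/run label for the `model` column.
#' @return Data frame with `model`, `criterion`, `threshold_pct`, `mean_pct`,
#'   `sd_pct`, `n_movies`.
#' @export
summarize_to_table <- function(stats, label = NULL) {
  if (is.null(stats) || nrow(stats$stats) == 0L) {
    return(data.frame(model = character(), criterion = character(),
                      threshold_pct = numeric(), mean_pct = numeric(),
                      sd_pct = numeric(), n_movies = integer()))
  }
  s <- stats$stats
  data.frame(
    model = if (is.null(label)) stats$design$growth$mode else label,
    criterion = stats$design$criterion,
    threshold_pct = 100 * s$threshold,
    mean_pct = 100 * s$mean_fraction,
    sd_pct = 100 * s$sd_fraction,
    n_movies = s$n_movies
  )
}
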