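test_that("zero-motion colonies always pass the 50% threshold", {
  d <- experiment_design(n_batches = 3, batch_size = 10,
                         migration = migration_params(speed = 0),
                         criterion = "throughout", seed = 4)
  r <- run_experiment(d)
  s <- r$stats[r$stats$threshold == 0.5, ]
  expect_equal(s$mean_fraction, 1)
  expect_equal(s$sd_fraction, 0)
})

test_that("across-batch mean equals the pooled pass fraction", {
  d <- experiment_design(n_batches = 5, batch_size = 20, duration = 48,
                         seed = 8)
  r <- run_experiment(d)
  expect_equal(r$stats$mean_fraction, unname(colMeans(r$batch_fractions)))
  expect_equal(r$stats$n_pass / r$stats$n_movies, r$stats$mean_fraction)
  expect_equal(r$stats$sd_fraction,
               unname(apply(r$batch_fractions, 2, sd)))
  # nested thresholds
  expect_lte(r$stats$n_pass[r$stats$threshold == 0.9],
             r$stats$n_pass[r$stats$threshold == 0.5])
})

test_that("single-movie batches reduce to Bernoulli sample statistics", {
  d <- experiment_design(n_batches = 40, batch_size = 1, duration = 48,
                         seed = 12)
  r <- run_experiment(d)
  expect_true(all(r$batch_fractions %in% c(0, 1)))
  expect_equal(r$stats$sd_fraction[1], sd(r$batch_fractions[, 1]))
})

test_that("per-movie substreams are stable when the design grows", {
  base <- experiment_design(n_batches = 2, batch_size = 10, duration = 24,
                            seed = 20)
  grown <- experiment_design(n_batches = 4, batch_size = 10, duration = 24,
                             seed = 20)
  rb <- run_experiment(base)
  rg <- run_experiment(grown)
  expect_equal(rb$batch_fractions, rg$batch_fractions[1:2, , drop = FALSE])
  expect_equal(run_experiment(base)$stats, rb$stats)
})

test_that("oversized designs are refused with a clear message", {
  d <- experiment_design(n_batches = 10, batch_size = 10, movie_cap = 50)
  expect_error(run_experiment(d), "cap")
})

test_that("throughput improvement is a guarded ratio", {
  expect_equal(throughput_improvement(0.723, 0.022), 32.86, tolerance = 1e-3)
  expect_equal(throughput_improvement(0.4, 0.4), 1)
  expect_equal(throughput_improvement(0, 0.5), 0)
  expect_error(throughput_improvement(0.7, 0), "lower bound")
})

test_that("summary tables surface percentages and nested thresholds", {
  fake <- structure(list(
    stats = data.frame(threshold = c(0.5, 0.9),
                       mean_fraction = c(0.245, 0.022),
                       sd_fraction = c(0.046, 0.016),
                       n_pass = c(24500, 2200), n_movies = 1e5),
    design = list(growth = list(mode = "synchronized"),
                  criterion = "throughout")), class = "batch_stats")
  tab <- summarize_to_table(fake)
  expect_equal(tab$model, rep("synchronized", 2))
  expect_equal(tab$threshold_pct, c(50, 90))
  expect_equal(tab$mean_pct, c(24.5, 2.2))
  expect_equal(tab$sd_pct, c(4.6, 1.6))
  expect_lte(tab$mean_pct[tab$threshold_pct == 90],
             tab$mean_pct[tab$threshold_pct == 50])
  expect_equal(nrow(summarize_to_table(NULL)), 0)
})
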