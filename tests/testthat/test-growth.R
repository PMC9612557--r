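test_that("synchronized counts double at every division epoch", {
  g <- growth_params()
  expect_equal(synchronized_cell_count(0, g), 1)
  expect_equal(synchronized_cell_count(96 * 60, g), 256)
  expect_equal(colony_radius_from_count(256, g), 120)
  expect_equal(synchronized_cell_count(11.99 * 60, g), 1)
  expect_equal(synchronized_cell_count(12 * 60, g), 2)
  expect_error(synchronized_cell_count(-1, g), ">= 0")
})

test_that("waiting-time rule reproduces the division-interval scale", {
  g <- growth_params()
  # deterministic stream: u = exp(-1) at n = 1 gives exactly the interval
  expect_equal(gillespie_waiting_time(exp(-1), 1, g), 720)
  set.seed(101)
  u <- runif(1e5)
  w1 <- gillespie_waiting_time(u, 1, g)
  se1 <- sd(w1) / sqrt(length(w1))
  expect_lt(abs(mean(w1) - 720), 3 * se1)
  w4 <- gillespie_waiting_time(u, 4, g)
  se4 <- sd(w4) / sqrt(length(w4))
  expect_lt(abs(mean(w4) - 180), 3 * se4)
})

test_that("division times are sorted, in range, and counts start at one", {
  set.seed(5)
  for (k in 1:20) {
    dt <- gillespie_division_times(96, growth_params(mode = "gillespie"))
    expect_true(all(diff(dt) > 0))
    expect_true(all(dt > 0 & dt <= 96 * 60))
    counts <- findInterval(seq(0, 5760, by = 15), dt) + 1
    expect_equal(counts[1], 1)
    expect_true(all(diff(counts) >= 0))
  }
  expect_error(gillespie_division_times(0), "> 0")
})

test_that("vectorized birth process matches a naive event-by-event oracle", {
  g <- growth_params(mode = "gillespie")
  n_rep <- 3000
  set.seed(23)
  fast <- vapply(seq_len(n_rep), function(i) {
    findInterval(720, gillespie_division_times(12, g)) + 1
  }, numeric(1))
  naive <- vapply(seq_len(n_rep), function(i) oracle_birth_count(720),
                  numeric(1))
  se <- sqrt(var(fast) / n_rep + var(naive) / n_rep)
  expect_lt(abs(mean(fast) - mean(naive)), 3 * se)
  # pure-birth mean at one interval is e^1
  expect_lt(abs(mean(fast) - exp(1)), 3 * sqrt(var(fast) / n_rep))
})

test_that("colony area is conserved: radius^2 = n * r1^2", {
  g <- growth_params(r1 = 7.5)
  n <- c(1, 2, 7, 100, 256)
  expect_equal(colony_radius_from_count(n, g)^2, n * 7.5^2)
})

test_that("parameter constructors validate their domains", {
  expect_error(growth_params(r1 = 0), "r1")
  expect_error(growth_params(division_interval = -2), "division_interval")
  expect_error(growth_params(mode = "other"))
  expect_error(migration_params(speed = -1), "speed")
  expect_error(migration_params(step_interval = 4, frame_interval = 15),
               "integer multiple")
  m <- migration_convention("per-frame")
  expect_equal(m$step_length, 15)
  expect_equal(migration_convention("per-minute")$step_length, 1)
})
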