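test_that("a motionless colony reduces to pure disk-FOV geometry", {
  m <- simulate_movie(migration = migration_params(speed = 0),
                      duration = 96, seed = 1)
  expect_true(all(m$x == 0) && all(m$y == 0))
  ref <- capture_fraction_xyr(0, 0, m$radius, m$fov)
  expect_equal(m$capture_fraction, ref)
  expect_equal(m$min_fraction, 0.951, tolerance = 1e-3)
  expect_equal(m$n_cells[length(m$n_cells)], 256)
})

test_that("zero-duration movies are a single fully captured frame", {
  m <- simulate_movie(duration = 0, seed = 2)
  expect_equal(length(m$times), 1L)
  expect_equal(m$capture_fraction, 1)
  mg <- simulate_movie(growth = growth_params(mode = "gillespie"),
                       duration = 0, seed = 2)
  expect_equal(mg$capture_fraction, 1)
})

test_that("movies are deterministic given a seed and frame counts are exact", {
  m1 <- simulate_movie(duration = 24, seed = 99)
  m2 <- simulate_movie(duration = 24, seed = 99)
  expect_identical(m1$capture_fraction, m2$capture_fraction)
  expect_identical(m1$x, m2$x)
  expect_equal(length(m1$times), 24 * 60 / 15 + 1)
  g <- simulate_movie(growth = growth_params(mode = "gillespie"),
                      duration = 24, seed = 99)
  g2 <- simulate_movie(growth = growth_params(mode = "gillespie"),
                       duration = 24, seed = 99)
  expect_identical(g$n_cells, g2$n_cells)
  expect_true(all(diff(g$n_cells) >= 0))
})

test_that("capture fraction is 1 whenever the disk is inside the FOV", {
  m <- simulate_movie(duration = 36, seed = 7)
  hw <- m$fov$width / 2
  inside <- abs(m$x) <= hw - m$radius & abs(m$y) <= hw - m$radius
  expect_true(all(m$capture_fraction[inside] == 1))
})

test_that("threshold classification follows the chosen criterion", {
  expect_equal(unname(classify_capture(list(capture_fraction = c(1, 1)))),
               c(TRUE, TRUE))
  expect_equal(unname(classify_capture(list(capture_fraction = c(1, 0.7)))),
               c(TRUE, FALSE))
  tr <- list(capture_fraction = c(1.0, 0.95, 0.91))
  expect_true(classify_capture(tr, 0.9, "throughout"))
  falling <- list(capture_fraction = c(1, 0.6, 0.95))
  expect_false(classify_capture(falling, 0.9, "throughout"))
  expect_true(classify_capture(falling, 0.9, "final_frame"))
  expect_error(classify_capture(list(capture_fraction = numeric(0))),
               "empty")
  expect_error(classify_capture(tr, thresholds = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("movie results flatten to one row per frame", {
  m <- simulate_movie(duration = 6, seed = 3)
  df <- as.data.frame(m, movie_id = 42L)
  expect_equal(nrow(df), length(m$times))
  expect_equal(names(df), c("movie_id", "time_min", "n_cells", "radius_um",
                            "x_um", "y_um", "capture_fraction"))
  expect_true(all(df$movie_id == 42L))
})
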