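test_that("fov_from_camera multiplies pixel counts by pixel size", {
  f <- fov_from_camera(1024, 1024, 0.2167)
  expect_equal(f$width, 221.9008)
  expect_equal(f$height, 221.9008)
  expect_equal(fov_from_camera(1, 1, 1)$width, 1)
  f2 <- fov_from_camera(1024, 512, 0.2167)
  expect_equal(c(f2$width, f2$height), c(221.9008, 110.9504))
  expect_error(fov_from_camera(0, 1024, 0.2167), "positive")
  expect_error(fov_from_camera(1024, 1024, -1), "positive")
})

test_that("disk overlap handles containment, disjointness and half-planes", {
  f <- fov_default()
  expect_equal(disk_rect_overlap_fraction(disk(0, 0, 50), f), 1)
  expect_equal(disk_rect_overlap_fraction(disk(500, 0, 7.5), f), 0)
  # disk centered on the midpoint of one edge of a much larger square
  big <- fov_from_camera(1000, 1000, 1)
  expect_equal(disk_rect_overlap_fraction(disk(500, 0, 10), big), 0.5,
               tolerance = 1e-12)
  expect_equal(disk_rect_overlap_fraction(disk(0, -500, 10), big), 0.5,
               tolerance = 1e-12)
  # zero radius: point containment
  expect_equal(disk_rect_overlap_fraction(disk(0, 0, 0), f), 1)
  expect_equal(disk_rect_overlap_fraction(disk(500, 0, 0), f), 0)
  expect_error(disk(0, 0, -1), ">= 0")
})

test_that("a 120-um colony centered in the default FOV keeps ~95.1% in view", {
  f <- fov_default()
  cf <- disk_rect_overlap_fraction(disk(0, 0, 120), f)
  expect_equal(cf, 0.951, tolerance = 1e-3)
  set.seed(42)
  mc <- mc_disk_fraction(0, 0, 120, f, n = 1e6)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(cf - mc), 3 * se)
})

test_that("closed-form overlap agrees with an independent piecewise integral", {
  f <- fov_default()
  hw <- f$width / 2
  set.seed(7)
  n <- 400
  x <- runif(n, -300, 300); y <- runif(n, -300, 300)
  r <- runif(n, 0.05, 450)
  got <- capture_fraction_xyr(x, y, r, f)
  ref <- vapply(seq_len(n), function(i) {
    min(max(colonycapture:::circle_rect_area(x[i], y[i], r[i],
                                             -hw, hw, -hw, hw) /
              (pi * r[i]^2), 0), 1)
  }, numeric(1))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("overlap fraction respects the square's dihedral symmetry", {
  f <- fov_default()
  set.seed(11)
  for (k in 1:25) {
    x <- runif(1, -200, 200); y <- runif(1, -200, 200)
    r <- runif(1, 1, 250)
    base <- capture_fraction_xyr(x, y, r, f)
    sym <- capture_fraction_xyr(
      c(-x, x, -x, y, -y, y, -y),
      c(y, -y, -y, x, x, -x, -x), r, f)
    expect_equal(sym, rep(base, 7), tolerance = 1e-12)
  }
})

test_that("overlap fraction is non-increasing as the center moves outward", {
  f <- fov_default()
  set.seed(13)
  for (k in 1:10) {
    r <- runif(1, 5, 200)
    y <- runif(1, -100, 100)
    fr <- capture_fraction_xyr(seq(0, 400, by = 5), y, r, f)
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("overlap matches the Monte-Carlo point-sampling oracle", {
  f <- fov_default()
  set.seed(17)
  n_pts <- 1e5
  for (k in 1:100) {
    x <- runif(1, -250, 250); y <- runif(1, -250, 250)
    r <- runif(1, 1, 300)
    cf <- capture_fraction_xyr(x, y, r, f)
    mc <- mc_disk_fraction(x, y, r, f, n = n_pts)
    se <- sqrt(max(mc * (1 - mc), 1e-12) / n_pts) + 1e-9
    expect_lt(abs(cf - mc), 3 * se + 1e-4)
  }
})
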