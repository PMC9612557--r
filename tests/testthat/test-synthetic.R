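test_that("colony placement is compact, circular and non-overlapping", {
  set.seed(71)
  expect_equal(place_cells_in_colony(1, c(3, -4)),
               matrix(c(3, -4), 1, 2, dimnames = list(NULL, c("x", "y"))))
  p7 <- place_cells_in_colony(7, c(0, 0), r1 = 7.5)
  expect_equal(nrow(p7), 7)
  expect_gte(min(dist(p7)), 2 * 7.5 * 0.9)
  expect_lte(max(sqrt(rowSums(p7^2))), 3 * 7.5)
  p256 <- place_cells_in_colony(256, c(0, 0), r1 = 7.5)
  expect_gte(min(dist(p256)), 2 * 7.5 * 0.9)
  enclosing <- max(sqrt(rowSums(p256^2))) + 7.5
  expect_lt(abs(enclosing - 120) / 120, 0.15)
  expect_error(place_cells_in_colony(0), ">= 1")
})

test_that("rendering reproduces background, spots and illumination exactly", {
  fov <- fov_from_camera(64, 64, 0.8672)
  flat <- render_config(illumination = c(1, 0, 0, 0, 0, 0), background = 50)
  # no cells, no noise, flat illumination: constant background
  img0 <- render_frame(data.frame(), fov, flat, noise = FALSE)
  expect_true(all(img0 == 50))
  # one centered cell: argmax at center, mass above background ~ brightness
  one <- render_frame(data.frame(x = 0, y = 0, brightness = 5e4), fov, flat,
                      noise = FALSE)
  peak <- arrayInd(which.max(one), dim(one))
  expect_true(all(abs(peak - 32.5) <= 1))
  expect_equal(sum(one - 50), 5e4, tolerance = 0.01 * 5e4)
  # known paraboloid, no cells: image / background equals the surface
  cfg <- render_config(illumination = c(1.2, 1e-3, -2e-3, -4e-5, -3e-5, 1e-5),
                       background = 80)
  imgp <- render_frame(data.frame(), fov, cfg, noise = FALSE)
  expect_equal(imgp / 80, paraboloid_surface(cfg$illumination, fov),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("in-FOV spot masses add to the summed brightnesses within 1%", {
  fov <- fov_from_camera(128, 128, 0.8672)
  flat <- render_config(illumination = c(1, 0, 0, 0, 0, 0), background = 10)
  set.seed(73)
  cells <- data.frame(x = runif(5, -30, 30), y = runif(5, -30, 30),
                      brightness = runif(5, 1e4, 1e5))
  img <- render_frame(cells, fov, flat, noise = FALSE)
  expect_equal(sum(img - 10), sum(cells$brightness),
               tolerance = 0.01 * sum(cells$brightness))
})

test_that("ground-truth cell counts follow the growth model every frame", {
  fov <- fov_from_camera(128, 128, 0.8672)
  mv <- make_movie(duration = 24, fov = fov, seed = 75)
  counts <- table(mv$truth$frame)
  expect_equal(as.vector(counts),
               as.vector(synchronized_cell_count(mv$times, mv$growth)))
  expect_equal(sum(mv$truth$frame == length(mv$frames)), 4)
  expect_equal(nrow(mv$divisions), 3)
  # zero duration: one frame, one cell
  mv0 <- make_movie(duration = 0, fov = fov, seed = 75)
  expect_equal(length(mv0$frames), 1L)
  expect_equal(nrow(mv0$truth), 1L)
})

test_that("lineage records form a forest with unique births", {
  fov <- fov_from_camera(128, 128, 0.8672)
  mv <- make_movie(duration = 30, fov = fov, seed = 77,
                   growth = growth_params(mode = "gillespie"))
  births <- tapply(mv$truth$frame, mv$truth$cell_id, min)
  expect_equal(length(births), length(unique(mv$truth$cell_id)))
  kids <- mv$truth[!is.na(mv$truth$parent_id), ]
  expect_true(all(kids$parent_id %in% mv$truth$cell_id))
  # a parent has exactly two children
  if (nrow(mv$divisions)) {
    nk <- table(unique(mv$truth[!is.na(mv$truth$parent_id),
                                c("cell_id", "parent_id")])$parent_id)
    expect_true(all(nk == 2))
  }
})

test_that("movies are bit-identical for a fixed seed and survive TIFF IO", {
  fov <- fov_from_camera(64, 64, 0.8672)
  a <- make_movie(duration = 6, fov = fov, seed = 79)
  b <- make_movie(duration = 6, fov = fov, seed = 79)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(a, path)
  back <- read_movie_tiff(path)
  expect_equal(length(back), length(a$frames))
  expect_equal(back[[3]], unclass(a$frames[[3]]), tolerance = 1e-9,
               ignore_attr = TRUE)
  unlink(path)
})
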