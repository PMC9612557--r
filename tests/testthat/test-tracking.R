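test_that("clean trajectories pass through the heuristics unchanged", {
  det <- lapply(1:5, function(f) {
    det_row(c(10 + f, 80), c(10, 80 - f), c(500, 900))
  })
  res <- resolve_discontinuities(link_tracks(det))
  expect_equal(length(unique(res$tracks$track_id)), 2L)
  expect_equal(nrow(res$divisions), 0L)
  expect_true(all(res$census$n_tracked == 2L))
  expect_equal(sort(unique(res$tracks$frame)), 1:5)
})

test_that("a single synthetic division is called at the right frame", {
  mv <- make_movie(duration = 13, fov = fov_small(), seed = 111)
  expect_equal(nrow(mv$divisions), 1L)
  tr <- track_movie(mv$frames)
  expect_equal(nrow(tr$divisions), 1L)
  expect_lte(abs(tr$divisions$frame - mv$divisions$frame), 1L)
  ev <- evaluate_tracking(tr, mv)
  expect_equal(ev$division_recall, 1)
  expect_equal(ev$link_recovery, 1)
})

test_that("a transient merge is repaired so both tracks span the movie", {
  # B approaches A, they merge for two frames, then separate again
  det <- list(
    det_row(c(50, 80), 50, c(1000, 800)),
    det_row(c(50, 75), 50, c(1000, 800)),
    det_row(c(50, 70), 50, c(1000, 800)),
    det_row(60, 50, 1830),
    det_row(60, 50, 1825),
    det_row(c(55, 65), 50, c(1010, 795)),
    det_row(c(54, 66), 50, c(1005, 800)),
    det_row(c(53, 67), 50, c(1000, 805)))
  res <- resolve_discontinuities(link_tracks(det))
  spans <- tapply(res$tracks$frame, res$tracks$track_id,
                  function(f) c(min(f), max(f)))
  expect_equal(length(spans), 2L)
  expect_true(all(vapply(spans, identical, TRUE, c(1, 8))))
  expect_equal(nrow(res$divisions), 0L)
  expect_true(all(res$census$n_tracked[c(4, 5)] == 2L))
})

test_that("capture fraction counts tracked cells against expectations", {
  census <- data.frame(frame = 1:4, n_tracked = c(2, 2, 2, 1))
  full <- lineage_capture_fraction(census, expected = c(2, 2, 2, 2))
  expect_equal(full$fraction, 0.5)
  expect_true(full$passes[["ge_0.5"]])
  expect_false(full$passes[["ge_0.9"]])
  all_in <- lineage_capture_fraction(census, expected = c(2, 2, 2, 1))
  expect_equal(all_in$fraction, 1)
  expect_error(lineage_capture_fraction(census, expected = c(2, 2, 0, 2)),
               "> 0")
  expect_error(lineage_capture_fraction(census, expected = c(2, 2)),
               "every frame")
})

test_that("tracked capture agrees with the geometric capture fraction", {
  # durations sit between division epochs: just-born sister nuclei overlap
  # into one blob for a frame, so a movie must not end mid-division
  for (s in c(121, 122)) {
    mv <- make_movie(duration = 45, fov = fov_small(), seed = s)
    tr <- track_movie(mv$frames)
    expected <- as.vector(table(mv$truth$frame))
    cap <- lineage_capture_fraction(tr, expected)
    radius <- colony_radius_from_count(expected, mv$growth)
    geo <- min(capture_fraction_xyr(mv$center[, 1], mv$center[, 2],
                                    radius, mv$fov))
    expect_lt(abs(cap$fraction - geo), 0.1)
  }
})

test_that("tracks serialize to CSV and a JSON forest", {
  mv <- make_movie(duration = 13, fov = fov_small(), seed = 123)
  tr <- track_movie(mv$frames)
  csv <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(tr$tracks))
  expect_equal(names(back), c("frame", "track_id", "parent_id", "x_px",
                              "y_px", "intensity", "area"))
  js <- jsonlite::fromJSON(lineage_to_json(tr))
  expect_equal(nrow(js), length(unique(tr$tracks$track_id)))
  unlink(csv)
})
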