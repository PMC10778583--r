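test_that("calibration validates its factors and converts exactly", {
  cal <- calibration(0.2, 4)
  expect_equal(px_to_um(10, cal), 2)
  expect_equal(um_to_px(2, cal), 10)
  expect_equal(frames_to_s(30, cal), 120)
  expect_error(calibration(0, 4))
  expect_error(calibration(0.2, -1))
})

test_that("calibrated_movie enforces consistent frame shapes", {
  f <- matrix(0, 8, 8)
  m <- calibrated_movie(list(f, f), cal02)
  expect_equal(length(m), 2L)
  expect_error(calibrated_movie(list(f, matrix(0, 8, 9)), cal02),
               "identical width and height")
})

test_that("write/read round-trips a simulated movie exactly", {
  sim <- simulate_movie(small_scene(seed = 11))
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie(sim$movie, path)
  back <- read_movie(path)
  expect_equal(length(back), length(sim$movie))
  for (t in seq_along(back$frames))
    expect_equal(back$frames[[t]], sim$movie$frames[[t]],
                 ignore_attr = TRUE)
  expect_equal(back$calibration$pixel_size, sim$movie$calibration$pixel_size,
               tolerance = 1e-6)
  expect_equal(back$calibration$frame_interval,
               sim$movie$calibration$frame_interval, tolerance = 1e-6)
})

test_that("explicit calibration arguments beat file metadata", {
  sim <- simulate_movie(small_scene(seed = 11))
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie(sim$movie, path)
  back <- read_movie(path, pixel_size = 0.5, frame_interval = 2)
  expect_equal(back$calibration$pixel_size, 0.5)
  expect_equal(back$calibration$frame_interval, 2)
})

test_that("a single-page TIFF yields a one-frame movie valid for morphology", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "single.tif")
  frame <- matrix(c(rep(10, 200), rep(200, 56)), 16, 16)
  tiff::writeTIFF(frame / 65535, path, bits.per.sample = 16L)
  m <- read_movie(path, pixel_size = 0.2, frame_interval = 4)
  expect_equal(length(m), 1L)
  p <- measure_morphology(m, pipeline_config(threshold_method = 100))
  expect_gt(nrow(p), 0)
})

test_that("reading without any calibration source is an error", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nocal.tif")
  tiff::writeTIFF(matrix(0.1, 8, 8), path, bits.per.sample = 16L)
  expect_error(read_movie(path), "pixel size")
  expect_error(read_movie(path, pixel_size = 0.2), "frame interval")
  expect_error(read_movie(file.path(dir, "absent.tif")), "not found")
})

test_that("multi-channel input is rejected", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rgb.tif")
  tiff::writeTIFF(array(0.5, c(8, 8, 3)), path, bits.per.sample = 8L)
  expect_error(read_movie(path, pixel_size = 0.2, frame_interval = 4),
               "single-channel")
})

test_that("write_tables writes the four CSVs with deterministic content", {
  dir <- withr::local_tempdir()
  spots <- data.frame(frame = c(2L, 1L, 1L), x_um = c(1, 3, 2),
                      y_um = c(1, 1, 1), quality = c(5, 6, 7))
  tracks <- data.frame(track_id = 1L, n_spots = 2L, first_frame = 1L,
                       last_frame = 2L, displacement_um = 5.0,
                       mean_speed_um_per_s = 1.25, motile = 1L)
  paths <- write_tables(spots, tracks, empty_particles <- data.frame(),
                        data.frame(), dir)
  expect_true(all(file.exists(paths)))
  sp <- read.csv(paths[["spots"]])
  expect_equal(sp$frame, c(1L, 1L, 2L))      # frame, then y, then x
  expect_equal(sp$x_um, c(2, 3, 1))
  tr <- read.csv(paths[["tracks"]])
  expect_equal(tr$displacement_um, 5.0)

  # empty tracks table -> header only
  write_tables(spots, mitomotion:::empty_tracks_table(), data.frame(),
               data.frame(), dir)
  lines <- readLines(paths[["tracks"]])
  expect_length(lines, 1L)

  # byte-identical on rerun
  first <- lapply(paths, readBin, what = "raw", n = 1e6)
  write_tables(spots, tracks, data.frame(), data.frame(), dir)
  expect_identical(readBin(paths[["spots"]], "raw", 1e6), first[["spots"]])
})

test_that("exported physical coordinates are pixel coordinates times calibration", {
  frame <- matrix(0, 40, 40)
  sig <- (1.5 / 2) / sqrt(2) / 0.2
  frame <- frame + outer(0:39, 0:39, function(y, x)
    100 * exp(-((x - 10)^2 + (y - 20)^2) / (2 * sig^2)))
  sp <- detect_spots(frame, pipeline_config(), cal02, 1L)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$x_um, 2.0, tolerance = 1e-4)
  expect_equal(sp$y_um, 4.0, tolerance = 1e-4)
})
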