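test_that("the morphology frame is selected by configured index", {
  frames <- lapply(1:6, function(i) matrix(i, 4, 4))
  m <- calibrated_movie(frames, cal02)
  expect_equal(select_morphology_frame(m, pipeline_config())[1, 1], 1)
  expect_equal(select_morphology_frame(
    m, pipeline_config(morphology_frame_index = 5))[1, 1], 5)
  one <- calibrated_movie(frames[1], cal02)
  expect_equal(select_morphology_frame(one, pipeline_config())[1, 1], 1)
  expect_error(select_morphology_frame(
    one, pipeline_config(morphology_frame_index = 2)), "out of range")
})

test_that("fixed and Otsu thresholds agree on a two-level image", {
  frame <- matrix(10, 32, 32)
  frame[10:20, 10:20] <- 100
  m_fixed <- segment(frame, 50)
  expect_equal(sum(m_fixed), 11 * 11)
  expect_identical(segment(frame, "otsu"), m_fixed)
  expect_equal(sum(segment(matrix(0, 8, 8), 1)), 0L)
  expect_error(segment(matrix(5, 8, 8), "otsu"), "fixed threshold")
})

test_that("the area gate excludes strictly below/above and keeps the bounds", {
  # pixel_size 0.1 -> 0.01 um^2/px: components of 10, 20, 490, 520 px
  cal <- calibration(0.1, 4)
  mask <- matrix(FALSE, 60, 60)
  mask[2, 2:11] <- TRUE                    # 1 x 10 px = 0.1 um^2
  mask[6, 2:21] <- TRUE                    # 1 x 20 px = 0.2 um^2
  mask[10:23, 2:36] <- TRUE                # 14 x 35   = 4.9 um^2
  mask[30:42, 2:41] <- TRUE                # 13 x 40   = 5.2 um^2
  p <- extract_particles(mask, cal, pipeline_config())
  expect_equal(attr(p, "n_total_components"), 4L)
  expect_equal(sort(p$area_um2), c(0.2, 4.9))
  expect_equal(attr(p, "n_excluded"), 2L)
})

test_that("areas count pixels and diagonal contact joins components", {
  mask <- matrix(FALSE, 12, 12)
  mask[3:7, 3:7] <- TRUE
  p <- extract_particles(mask, cal02, pipeline_config())
  expect_equal(p$area_um2, 1.0)

  diag_mask <- matrix(FALSE, 8, 8)
  diag_mask[2, 2] <- TRUE; diag_mask[3, 3] <- TRUE
  lab <- mitomotion:::label_components_cpp(diag_mask)
  expect_equal(max(lab), 1L)
})

test_that("Feret diameter equals pixel-corner geometry", {
  expect_equal(feret_diameter(cbind(5, 7), cal02), 0.2 * sqrt(2))
  # axis-aligned 6 x 3 rectangle: corner-to-corner diagonal of the box
  rect <- as.matrix(expand.grid(x = 0:5, y = 0:2))
  expect_equal(feret_diameter(rect, cal02), 0.2 * sqrt(36 + 9))
  set.seed(9)
  for (rep in 1:25) {
    comp <- random_component(sample(2:40, 1))
    expect_equal(feret_diameter(comp, cal02), brute_feret(comp, 0.2),
                 tolerance = 1e-12)
  }
})

test_that("aspect ratio reflects elongation and stays finite", {
  # disk of radius 10 px
  disk <- which(outer(-15:15, -15:15, function(y, x) x^2 + y^2 <= 100),
                arr.ind = TRUE)
  expect_equal(aspect_ratio(disk[, c(2, 1)]), 1.0, tolerance = 0.05)
  rect <- as.matrix(expand.grid(x = 0:19, y = 0:4))   # 20 x 5
  expect_equal(aspect_ratio(rect), 4.0, tolerance = 0.15)
  line <- cbind(0:9, 0)                               # 1-px-wide line
  ar <- aspect_ratio(line)
  expect_true(is.finite(ar) && ar >= 5)
  expect_equal(aspect_ratio(cbind(3, 3)), 1.0)
})

test_that("a rasterized 3 x 1 um ellipse is measured within 10% at any angle", {
  for (phi in seq(0, 5 * pi / 6, by = pi / 6)) {
    mask <- raster_ellipse(1.5, 0.5, phi, 0.1, field_px = 64)
    cal <- calibration(0.1, 4)
    p <- extract_particles(mask, cal, pipeline_config())
    expect_equal(nrow(p), 1L)
    expect_lt(abs(p$area_um2 - pi * 1.5 * 0.5) / (pi * 1.5 * 0.5), 0.10)
    expect_lt(abs(p$aspect_ratio - 3) / 3, 0.10)
    expect_lt(abs(p$feret_um - 3) / 3, 0.10)
  }
})

test_that("widening the gate never drops a particle and counts are conserved", {
  sim <- simulate_movie(small_scene(seed = 35))
  mask <- segment(sim$movie$frames[[1]], 60)
  narrow <- extract_particles(mask, cal02,
                              pipeline_config(min_particle_area = 0.4,
                                              max_particle_area = 2))
  wide <- extract_particles(mask, cal02,
                            pipeline_config(min_particle_area = 0.2,
                                            max_particle_area = 5))
  expect_true(all(narrow$area_um2 %in% wide$area_um2))
  expect_equal(attr(wide, "n_total_components"),
               nrow(wide) + attr(wide, "n_excluded"))
  expect_equal(attr(narrow, "n_total_components"),
               nrow(narrow) + attr(narrow, "n_excluded"))
})
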