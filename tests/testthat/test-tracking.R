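make_track <- function(xy, first_frame = 1L) {
  data.frame(frame = seq_len(nrow(xy)) + first_frame - 1L,
             x_um = xy[, 1], y_um = xy[, 2], quality = 1)
}

test_that("linking respects the hard distance cutoff", {
  a <- data.frame(x_um = 0, y_um = 0)
  expect_equal(nrow(link_frame_pair(a, data.frame(x_um = 0, y_um = 1.9), 2)), 1L)
  expect_equal(nrow(link_frame_pair(a, data.frame(x_um = 0, y_um = 2.1), 2)), 0L)
  expect_equal(nrow(link_frame_pair(data.frame(x_um = numeric(),
                                               y_um = numeric()), a, 2)), 0L)
})

test_that("linking is optimal against exhaustive enumeration", {
  set.seed(42)
  for (rep in 1:40) {
    sa <- random_spots(sample(0:6, 1))
    sb <- random_spots(sample(0:6, 1))
    cutoff <- runif(1, 0.5, 4)
    m <- link_frame_pair(sa, sb, cutoff)
    got <- link_cost(m, sa, sb)
    want <- brute_link_cost(sa, sb, cutoff)
    expect_equal(got$card, max(want$card, 0L))
    expect_equal(got$cost, max(want$cost * (want$card > 0), 0),
                 tolerance = 1e-10)
  }
})

test_that("an unambiguous chain forms a single full-length track", {
  spots <- lapply(1:31, function(t)
    data.frame(frame = t, x_um = 0.1 * t, y_um = 0, quality = 1))
  tracks <- build_tracks(spots, pipeline_config())
  expect_length(tracks, 1L)
  expect_equal(nrow(tracks[[1]]), 31L)
})

test_that("a missed detection splits a track; gaps are never closed", {
  spots <- lapply(1:8, function(t) {
    if (t == 4) return(data.frame(frame = integer(), x_um = numeric(),
                                  y_um = numeric(), quality = numeric()))
    data.frame(frame = t, x_um = 0.1 * t, y_um = 0, quality = 1)
  })
  tracks <- build_tracks(spots, pipeline_config())
  expect_length(tracks, 2L)
  expect_equal(vapply(tracks, nrow, integer(1)), c(3L, 4L))
  for (tr in tracks) expect_true(all(diff(tr$frame) == 1L))
})

test_that("singleton chains are not emitted", {
  spots <- list(data.frame(frame = 1L, x_um = c(0, 10), y_um = c(0, 0),
                           quality = 1),
                data.frame(frame = 2L, x_um = 0.1, y_um = 0, quality = 1))
  tracks <- build_tracks(spots, pipeline_config())
  expect_length(tracks, 1L)   # the spot at x = 10 stays unlinked
})

test_that("spot conservation holds per frame on simulated scenes", {
  scene <- small_scene(seed = 31)
  sim <- simulate_movie(scene)
  cfg <- scene_matched_config(scene)
  spots <- detect_movie(sim$movie, cfg)
  tracks <- build_tracks(spots, cfg)
  for (t in seq_along(spots)) {
    in_tracks <- sum(vapply(tracks, function(tr) sum(tr$frame == t),
                            numeric(1)))
    expect_lte(in_tracks, nrow(spots[[t]]))
  }
  total_in_tracks <- sum(vapply(tracks, nrow, integer(1)))
  total <- sum(vapply(spots, nrow, integer(1)))
  expect_lte(total_in_tracks, total)
})

test_that("displacement and speed follow their definitions", {
  t345 <- make_track(cbind(c(0, 1, 3), c(0, 2, 4)))
  expect_equal(track_displacement(t345), 5)
  loop <- make_track(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  expect_equal(track_displacement(loop), 0)
  straight <- make_track(cbind(seq(0, 3, by = 0.1), 0))
  expect_equal(track_displacement(straight), 3)

  tr <- make_track(cbind(c(0, 1, 2), 0))
  expect_equal(track_mean_speed(tr, 4), 0.25)
  still <- make_track(cbind(c(1, 1), c(2, 2)))
  expect_equal(track_mean_speed(still, 4), 0)
  zig <- make_track(cbind(c(0, rep(c(0.6, 0), 5)), 0))  # 10 steps of 0.6 um
  expect_equal(track_mean_speed(zig, 4), 6 / 40)
})

test_that("the motility filter is strictly 'above'", {
  mk <- function(d) make_track(cbind(c(0, d), c(0, 0)))
  tracks <- lapply(c(0.5, 1.5, 1.6, 3.0), mk)
  kept <- filter_motile(tracks, 1.5)
  expect_equal(vapply(kept, track_displacement, numeric(1)), c(1.6, 3.0))
  expect_length(filter_motile(list(), 1.5), 0L)
  expect_length(filter_motile(tracks, 0), 4L)
})

test_that("displacement never exceeds path length on simulated tracks", {
  scene <- small_scene(seed = 32)
  sim <- simulate_movie(scene)
  cfg <- scene_matched_config(scene)
  tracks <- build_tracks(detect_movie(sim$movie, cfg), cfg)
  expect_gt(length(tracks), 0)
  for (tr in tracks) {
    path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
    expect_lte(track_displacement(tr), path + 1e-12)
  }
})

test_that("recovered tracks and speeds match simulator ground truth", {
  scene <- scene_config(seed = 33)
  sim <- simulate_movie(scene)
  cfg <- scene_matched_config(scene)
  res <- run_roi(sim$movie, cfg, register = FALSE)
  expect_equal(nrow(res$tracks_df), nrow(sim$truth$blobs))
  expect_equal(sum(res$tracks_df$motile), sum(sim$truth$blobs$motile))
  v_true <- mean(sim$truth$blobs$mean_speed_um_per_s[sim$truth$blobs$motile == 1])
  v_rec <- mean(res$tracks_df$mean_speed_um_per_s[res$tracks_df$motile == 1])
  expect_lt(abs(v_rec - v_true) / v_true, 0.10)
})
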