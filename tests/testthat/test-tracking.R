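test_that("the fixture renders droplets where the ground truth says", {
  meta <- video_meta()
  # empty trajectory set -> blank frames, empty ground truth
  empty <- list(tracks = data.frame(droplet_id = integer(0), t_s = numeric(0),
                                    x_mm = numeric(0), y_mm = numeric(0)),
                duration_s = 1)
  vid0 <- generate_synthetic_video(empty, meta)
  expect_equal(nrow(vid0$truth), 0L)
  expect_equal(diff(range(vid0$frames[[1]])), 0)

  # 4 stationary droplets in a Y pattern -> 4 constant ground-truth tracks
  pos <- curiodrop:::initial_positions(4)
  vid4 <- generate_synthetic_video(stationary_trajectories(pos, 2), meta)
  expect_equal(length(unique(vid4$truth$track_id)), 4L)
  for (id in 1:4) {
    sub <- vid4$truth[vid4$truth$track_id == id, ]
    expect_equal(diff(range(sub$x_mm)), 0)
    expect_equal(diff(range(sub$y_mm)), 0)
  }

  # noise-free single droplet: detected centroid within 0.5 px of truth
  one <- stationary_trajectories(matrix(c(3.13, -2.41), 1), 0.5)
  vid1 <- generate_synthetic_video(one, meta)
  det <- detect_droplets(vid1$frames[[1]], meta)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - vid1$truth$x_px[1]), 0.5)
  expect_lt(abs(det$y_px - vid1$truth$y_px[1]), 0.5)

  # trajectories outside the arena are rejected by the fixture
  outside <- stationary_trajectories(matrix(c(50, 0), 1), 1)
  expect_error(generate_synthetic_video(outside, meta), "fixture error")
})

test_that("detection finds dark blobs inside the arena", {
  meta <- video_meta()
  blank <- matrix(0.9, meta$height_px, meta$width_px)
  expect_equal(nrow(detect_droplets(blank, meta, threshold = 0.5)), 0L)

  pos <- curiodrop:::initial_positions(4)
  vid <- generate_synthetic_video(stationary_trajectories(pos, 0.5), meta)
  det <- detect_droplets(vid$frames[[1]], meta)
  expect_equal(nrow(det), 4L)
  truth1 <- vid$truth[vid$truth$frame == 0, ]
  for (i in seq_len(4)) {
    d <- sqrt((det$x_px - truth1$x_px[i])^2 + (det$y_px - truth1$y_px[i])^2)
    expect_lt(min(d), 0.5)
  }

  # two disks overlapping beyond the merge distance appear as one region
  close_pos <- matrix(c(0, 0, 1.0, 0), 2, byrow = TRUE)  # 1 mm apart
  vid2 <- generate_synthetic_video(stationary_trajectories(close_pos, 0.5),
                                   meta)
  expect_equal(nrow(detect_droplets(vid2$frames[[1]], meta)), 1L)
})

test_that("proximity linking preserves identity and handles events", {
  meta <- video_meta()
  pos <- curiodrop:::initial_positions(4)
  vid <- generate_synthetic_video(stationary_trajectories(pos, 1), meta)
  tk <- track_video(vid$frames, meta)
  tab <- tracks_table(tk)
  expect_equal(length(unique(tab$track_id)), 4L)
  per_track_frames <- table(tab$track_id)
  expect_true(all(per_track_frames == length(vid$frames)))

  base <- list(tracks = data.frame(
    droplet_id = rep(1:3, each = 2), t_s = rep(c(0, 10), 3),
    x_mm = rep(c(-6, 0, 6), each = 2), y_mm = rep(0, 6)),
    duration_s = 10)
  events <- list(list(type = "split", droplet_id = 2, t_s = 3),
                 list(type = "exit", droplet_id = 3, t_s = 2),
                 list(type = "fuse", droplet_id = 1, into = 2, t_s = 8))
  vev <- generate_synthetic_video(base, meta, events = events)
  tkev <- track_video(vev$frames, meta, max_link_speed_mm_s = 30)
  tab <- tracks_table(tkev)
  status <- unique(tab[, c("track_id", "status")])
  # split: one extra track with a new id
  expect_equal(length(unique(tab$track_id)), 4L)
  expect_true(4L %in% tab$track_id)
  # scripted rim exit closes with status exited
  expect_equal(status$status[status$track_id == 3], "exited")
  # scripted fuse closes with status fused
  expect_equal(status$status[status$track_id == 1], "fused")
})

test_that("behavior metrics recover analytic ground truth", {
  meta <- video_meta()
  # all droplets stationary -> mean speed 0, count 4
  pos <- curiodrop:::initial_positions(4)
  vid <- generate_synthetic_video(stationary_trajectories(pos, 2), meta)
  beh <- compute_behavior(track_video(vid$frames, meta))
  expect_equal(beh$observation[["mean_speed"]], 0)
  expect_equal(beh$observation[["mean_droplet_count"]], 4.0)

  # circular motion: v = r * omega = 5 mm * 0.4 rad/s = 2.0 mm/s
  vidc <- generate_synthetic_video(circle_trajectories(), meta)
  behc <- compute_behavior(track_video(vidc$frames, meta))
  expect_equal(behc$observation[["mean_speed"]], 2.0, tolerance = 0.02)
  expect_equal(behc$observation[["mean_droplet_count"]], 1.0)

  expect_error(compute_behavior(data.frame(track_id = integer(0),
                                           frame = integer(0),
                                           x_mm = numeric(0),
                                           y_mm = numeric(0)),
                                meta = meta),
               "invalid input")
})

test_that("speed metrics are invariant to a global intensity offset", {
  meta <- video_meta()
  vid <- generate_synthetic_video(circle_trajectories(duration_s = 5), meta)
  shifted <- lapply(vid$frames, function(f) pmin(f + 0.05, 1))
  beh0 <- compute_behavior(track_video(vid$frames, meta))
  beh1 <- compute_behavior(track_video(shifted, meta))
  expect_equal(beh1$observation[["mean_speed"]],
               beh0$observation[["mean_speed"]], tolerance = 0.01)
  expect_equal(beh1$observation[["mean_droplet_count"]],
               beh0$observation[["mean_droplet_count"]])
})

test_that("equidistant matches resolve to the lowest track id", {
  meta <- video_meta()
  tracker <- new_tracker(meta)
  d0 <- data.frame(x_px = c(90, 110), y_px = c(100, 100), area_px2 = 50)
  tracker <- link_detections(tracker, d0, 0L, max_link_distance_px = 15)
  # one detection exactly halfway between the two track heads
  d1 <- data.frame(x_px = 100, y_px = 100, area_px2 = 50)
  tracker <- link_detections(tracker, d1, 1L, max_link_distance_px = 15)
  tab <- tracks_table(tracker)
  expect_equal(nrow(tab[tab$track_id == 1, ]), 2L)
  expect_equal(nrow(tab[tab$track_id == 2, ]), 1L)
})
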