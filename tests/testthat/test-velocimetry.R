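test_that("particle detection finds sub-pixel centroids", {
  p <- tiny_vein(noise_sd = 0, duration = 0.1)
  sim <- simulate_flow_video(p)
  det <- detect_particles(sim$video$frames[1, , ])
  expect_equal(nrow(det), 3)
  # match each detection to the nearest true position
  for (k in seq_len(3)) {
    d <- sqrt((det[k, "x"] - sim$truth$x_px[1, ])^2 +
                (det[k, "y"] - sim$truth$y_px[1, ])^2)
    expect_lt(min(d), 0.5)
  }
  # blank frame: nothing to detect
  expect_equal(nrow(detect_particles(matrix(220L, 64, 64))), 0)
  # two cells separated by > 2 radii stay separate
  fr <- matrix(220L, 64, 64)
  fr[10:14, 10:14] <- 40L
  fr[10:14, 30:34] <- 40L
  expect_equal(nrow(detect_particles(fr)), 2)
})

test_that("linking builds one track per particle and resolves crossings", {
  # one particle drifting 3 px/frame for 10 frames
  det <- lapply(1:10, function(t) cbind(x = 5 + 3 * t, y = 20, n = 12))
  tr <- link_tracks(det, max_disp = 5)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 10)
  expect_equal(diff(tr[[1]]$frame), rep(1, 9))

  # vein simulation: three cells -> three long tracks on the true lanes
  sim <- simulate_flow_video(tiny_vein(duration = 0.2, seed = 5))
  dets <- lapply(seq_len(30), function(k)
    detect_particles(sim$video$frames[k, , ]))
  trk <- link_tracks(dets, max_disp = 10)
  long <- trk[vapply(trk, nrow, integer(1)) >= 10]
  ys <- vapply(long, function(t) mean(t$y), numeric(1))
  lanes <- sort(sim$truth$y_px[1, ])
  # every long track runs on a true lane (wrap-around may split a cell
  # into two tracks on the same lane), and all three lanes are covered
  nearest <- vapply(ys, function(y) min(abs(y - lanes)), numeric(1))
  expect_true(all(nearest < 0.1))
  expect_equal(sort(unique(vapply(ys, function(y)
    which.min(abs(y - lanes)), integer(1)))), 1:3)

  # crossing within max_disp: smallest-displacement pairing wins
  det2 <- list(cbind(x = c(10, 20), y = c(10, 10), n = 10),
               cbind(x = c(12, 18), y = c(10, 10), n = 10))
  tr2 <- link_tracks(det2, max_disp = 10)
  expect_equal(unname(vapply(tr2, function(t) unname(diff(t$x)), numeric(1))),
               c(2, -2))
})

test_that("track velocity converts pixels and frames to um/s", {
  tr <- data.frame(frame = 1:12, x = 5 * (1:12), y = 7)
  expect_equal(track_velocity(tr, fps = 150, pixel_size = 0.5), 375)
  still <- data.frame(frame = 1:12, x = 3, y = 3)
  expect_equal(track_velocity(still, fps = 150, pixel_size = 0.5), 0)
  expect_error(track_velocity(tr[1:5, ], fps = 150, pixel_size = 0.5),
               class = "zfcardio_insufficient_track")
})

test_that("vein flow is recovered within 2 percent", {
  sim <- simulate_flow_video(tiny_vein(seed = 2))
  rep <- flow_report(sim$video, "vein")
  expect_equal(rep$n_cells, 3)
  expect_lt(rel_err(rep$mean_velocity, 500), 0.02)
  expect_equal(rep$mean_velocity, mean(rep$cells$velocity_um_s))
})

test_that("aorta mode averages pulsatility out over whole tracks", {
  sim <- simulate_flow_video(aorta_params(seed = 4))
  rep <- flow_report(sim$video, "aorta", max_disp = 40)
  expect_lt(rel_err(rep$mean_velocity, 800), 0.03)
  # the 10-frame vein-style window during the accelerating phase
  # overestimates the mean: the motivation for whole-track scoring
  dets <- lapply(seq_len(dim(sim$video)[1]), function(k)
    detect_particles(sim$video$frames[k, , ]))
  trk <- link_tracks(dets, max_disp = 40)
  full <- trk[vapply(trk, nrow, integer(1)) >= 80][[1]]
  v10 <- track_velocity(full, sim$video$fps, sim$video$pixel_size, 10)
  expect_gt(v10, 800)
})

test_that("velocity is invariant to intensity scale and frame rate", {
  sim <- simulate_flow_video(tiny_vein(seed = 6, duration = 0.5))
  v1 <- flow_report(sim$video, "vein")$mean_velocity
  # halve the contrast globally (toward white): detections unchanged
  fr <- sim$video$frames
  fr2 <- 255L - (255L - fr) %/% 2L
  dim(fr2) <- dim(fr)
  v2 <- flow_report(video_sequence(fr2, sim$video$fps, sim$video$pixel_size),
                    "vein")$mean_velocity
  expect_equal(v2, v1, tolerance = 0.01)
  # doubling fps at the same physical velocity halves the per-frame
  # displacement but leaves the estimate unchanged
  s2 <- simulate_flow_video(tiny_vein(seed = 6, duration = 0.5, fps = 300))
  v3 <- flow_report(s2$video, "vein")$mean_velocity
  expect_equal(v3, v1, tolerance = 0.01)

  # two cells over 12 frames: wrap-around can split a track but never
  # yields three ten-frame tracks
  s1 <- simulate_flow_video(tiny_vein(n_cells = 2, duration = 0.08))
  expect_error(flow_report(s1$video, "vein"),
               class = "zfcardio_insufficient_cells")
})
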