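test_that("heart generator reproduces the acquisition geometry", {
  p <- heart_sim_params(width = 48, height = 48, pixel_size = 4,
                        fps = 150, duration = 10, heart_rate = 180,
                        noise_sd = 0)
  sim <- simulate_heart_video(p)
  expect_equal(dim(sim$video)[1], 1500)           # 150 fps x 10 s
  expect_equal(sim$truth$n_cycles, 30)            # 180 bpm over 10 s
  expect_equal(sim$truth$a_um[1], 120)            # frame 1 is end-diastole
  expect_equal(sim$truth$edv_um3, 402123.9, tolerance = 1e-6)
  expect_equal(sim$truth$esv_um3, ellipsoid_volume(100, 60))
})

test_that("no-contraction parameters give a constant series and zero truth", {
  p <- tiny_heart(a_s = 120, b_s = 80, noise_sd = 0)
  sim <- simulate_heart_video(p)
  expect_equal(diff(range(sim$truth$area_um2)), 0)
  expect_identical(sim$video$frames[1, , ], sim$video$frames[50, , ])
  expect_equal(sim$truth$sv_um3, 0)
  expect_equal(sim$truth$sf_pct, 0)
  expect_equal(sim$truth$ef_pct, 0)
  expect_equal(sim$truth$fac_pct, 0)
})

test_that("noiseless masks are recoverable by midpoint thresholding", {
  p <- tiny_heart(noise_sd = 0, duration = 0.5, store_masks = TRUE)
  sim <- simulate_heart_video(p)
  mid <- (p$fg + p$bg) / 2
  rec <- sim$video$frames > mid
  expect_identical(rec, sim$truth$masks)
})

test_that("generators are bit-reproducible in seed and parameters", {
  a <- simulate_heart_video(tiny_heart(seed = 7, duration = 0.5))
  b <- simulate_heart_video(tiny_heart(seed = 7, duration = 0.5))
  c <- simulate_heart_video(tiny_heart(seed = 8, duration = 0.5))
  expect_identical(a$video$frames, b$video$frames)
  expect_false(identical(a$video$frames, c$video$frames))

  f1 <- simulate_flow_video(tiny_vein(seed = 3, duration = 0.2))
  f2 <- simulate_flow_video(tiny_vein(seed = 3, duration = 0.2))
  expect_identical(f1$video$frames, f2$video$frames)

  v1 <- simulate_vessel_stack(tiny_torus(seed = 5))
  v2 <- simulate_vessel_stack(tiny_torus(seed = 5))
  expect_identical(v1$stack$voxels, v2$stack$voxels)
})

test_that("flow ground truth follows the advection law", {
  # vein: constant velocity, exact inter-frame displacement v / fps
  sim <- simulate_flow_video(tiny_vein(duration = 0.2, noise_sd = 0))
  dx <- diff(sim$truth$x_um[, 1])
  dx <- dx[dx > 0]                      # drop the wrap jump
  expect_equal(unique(round(dx, 10)), 500 / 150)   # 10/3 um exactly

  # v = 0: all cells stationary
  s0 <- simulate_flow_video(tiny_vein(velocity = 0, duration = 0.2))
  expect_equal(diff(range(s0$truth$x_um[, 1])), 0)

  # aorta: instantaneous velocity averages to v over whole pulses
  pa <- aorta_params(duration = 2)      # 5 pulses at 2.5 Hz
  sa <- simulate_flow_video(pa)
  expect_equal(mean(sa$truth$v_inst), 800, tolerance = 0.005)
})

test_that("vessel generator matches the torus closed form", {
  p <- vessel_sim_params(R = 50, r = 5)
  sim <- simulate_vessel_stack(p)
  expect_equal(sim$truth$ring_volume_um3, 24674.01, tolerance = 1e-6)
  # voxelised volume vs analytic torus (brute-force voxel count oracle)
  vox_vol <- sim$truth$ring_voxels * sim$truth$voxel_volume_um3
  expect_lt(rel_err(vox_vol, 2 * pi^2 * 50 * 25), 0.05)
  # without interferer the foreground is one 26-connected component
  lab <- zfcardio:::label_components_3d(sim$truth$ring_mask)
  expect_equal(max(lab), 1)
})

test_that("generator geometry violations raise errors", {
  expect_error(simulate_heart_video(tiny_heart(a_d = 400, b_d = 100)),
               class = "zfcardio_geometry")
  expect_error(flow_sim_params(width = 10, height = 10, pixel_size = 1,
                               cell_radius = 20),
               class = "zfcardio_geometry")
  expect_error(simulate_vessel_stack(tiny_torus(R = 80)),
               class = "zfcardio_geometry")
  expect_error(tiny_heart(a_s = 130), "diastolic")
  expect_error(flow_sim_params(mode = "aorta", pulsatility = 1.2),
               "pulsatility")
})
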