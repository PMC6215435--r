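test_that("ellipsoid volume follows the prolate-spheroid formula", {
  expect_equal(ellipsoid_volume(2, 1), 1.0472, tolerance = 1e-4)
  expect_equal(ellipsoid_volume(2, 2), 4 / 3 * pi)      # sphere, d = 2
  expect_equal(ellipsoid_volume(120, 80), 402123.9, tolerance = 1e-6)
  # b enters squared, a linearly
  expect_equal(ellipsoid_volume(200, 80), 2 * ellipsoid_volume(100, 80))
  expect_equal(ellipsoid_volume(100, 80), 4 * ellipsoid_volume(100, 40))
  expect_error(ellipsoid_volume(1, 2), "a >= b")
  expect_error(ellipsoid_volume(2, 0), "a >= b")
})

test_that("equal-moments ellipse recovers discs and rotated ellipses", {
  # disc of radius 50 px: a = b = 100 um within 2 percent, theta tie-break 0
  m <- outer(1:121, 1:121,
             function(r, c) (r - 61)^2 + (c - 61)^2 <= 50^2)
  f <- fit_ellipse(m, pixel_size = 1)
  expect_lt(rel_err(f$a, 100), 0.02)
  expect_lt(rel_err(f$b, 100), 0.02)
  expect_identical(f$theta, 0)

  # rasterised ellipse a = 100 px, b = 50 px at 30 degrees
  th0 <- 30 * pi / 180
  rr <- row(matrix(0, 140, 140)) - 70.5
  cc <- col(matrix(0, 140, 140)) - 70.5
  u <- cc * cos(th0) + rr * sin(th0)
  w <- -cc * sin(th0) + rr * cos(th0)
  m2 <- (u / 50)^2 + (w / 25)^2 <= 1
  f2 <- fit_ellipse(m2, pixel_size = 1)
  expect_lt(rel_err(f2$a, 100), 0.02)
  expect_lt(rel_err(f2$b, 50), 0.02)
  expect_lt(abs(f2$theta - th0), 2 * pi / 180)

  # area consistency: pi a b / 4 matches calibrated pixel count
  expect_lt(rel_err(pi * f2$a * f2$b / 4, sum(m2)), 0.02)

  # degenerate masks
  line <- matrix(FALSE, 10, 10); line[5, 2:9] <- TRUE
  expect_error(fit_ellipse(line, 1), class = "zfcardio_degenerate_region")
  expect_error(fit_ellipse(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), 1),
               class = "zfcardio_degenerate_region")
})

test_that("ventricle segmentation recovers the generator mask", {
  p <- tiny_heart(noise_sd = 0, duration = 0.1, store_masks = TRUE)
  sim <- simulate_heart_video(p)
  seg <- segment_ventricle(sim$video$frames[1, , ])
  expect_gte(dice(seg$mask, sim$truth$masks[1, , ]), 0.98)

  # 5 percent-of-range noise, seeded
  pn <- tiny_heart(noise_sd = 12.75, duration = 0.1, store_masks = TRUE,
                   seed = 11)
  simn <- simulate_heart_video(pn)
  segn <- segment_ventricle(simn$video$frames[1, , ])
  expect_gte(dice(segn$mask, simn$truth$masks[1, , ]), 0.95)

  expect_error(segment_ventricle(matrix(7L, 32, 32)),
               class = "zfcardio_no_object")
})

test_that("batched area series equals the per-frame chain", {
  sim <- simulate_heart_video(tiny_heart(duration = 0.2, seed = 3))
  ser <- area_series(sim$video)
  for (k in c(1, 5, 10)) {
    mk <- segment_ventricle(sim$video$frames[k, , ])
    fk <- fit_ellipse(mk, sim$video$pixel_size)
    expect_equal(ser$area_um2[k], mk$pixel_count * 4)
    expect_equal(ser$a_um[k], fk$a)
    expect_equal(ser$b_um[k], fk$b)
  }
  # constant-axes video: rasterisation jitter below 1 percent
  sc <- simulate_heart_video(tiny_heart(a_s = 120, b_s = 80, noise_sd = 3))
  serc <- area_series(sc$video)
  expect_lt(diff(range(serc$area_um2)) / mean(serc$area_um2), 0.01)
})

test_that("beat detection finds every cycle of a raised-cosine series", {
  tt <- (0:1499) / 150
  area <- 5000 + 1500 * (1 + cos(2 * pi * 3 * tt)) / 2
  ser <- detect_beats(make_series(area, fps = 150))
  expect_length(ser$diastole, 30)
  expect_length(ser$systole, 29)
  # alternation: every systole sits between its flanking diastoles
  expect_true(all(ser$systole > head(ser$diastole, -1) &
                    ser$systole < tail(ser$diastole, -1)))

  expect_error(detect_beats(make_series(rep(5000, 600), fps = 150)),
               class = "zfcardio_no_beat")
  expect_error(detect_beats(make_series(area[1:100], fps = 150)),
               class = "zfcardio_no_beat")
})

test_that("heart rate spans three beats between four diastoles", {
  ser <- make_series(rep(1, 200), fps = 150)
  ser$diastole <- c(1, 51, 101, 151)       # 1/3 s apart at 150 fps
  expect_equal(heart_rate(ser), 180)
  ser$diastole <- c(1, 76, 151, 226)       # 0.5 s apart
  expect_equal(heart_rate(ser, fps = 150), 120)
  ser$diastole <- c(1, 51, 101)
  expect_error(heart_rate(ser), class = "zfcardio_no_beat")
})

test_that("cardiac report satisfies its definitional identities", {
  sim <- simulate_heart_video(tiny_heart(seed = 2))
  rep <- cardiac_report(sim$video)
  expect_equal(rep$co_nl_min, rep$hr_bpm * rep$sv_nl)
  expect_equal(rep$ef_pct, rep$sv_um3 / rep$edv_um3 * 100)
  expect_equal(rep$sv_um3, mean(rep$beats$edv_um3 - rep$beats$esv_um3))
  expect_equal(rep$edv_um3, mean(rep$beats$edv_um3))
  expect_true(rep$edv_um3 >= rep$esv_um3)
  expect_gte(rep$sf_pct, 0); expect_lte(rep$sf_pct, 100)
  expect_gte(rep$fac_pct, 0); expect_lte(rep$fac_pct, 100)

  # recovery against generator truth
  expect_lt(rel_err(rep$edv_um3, sim$truth$edv_um3), 0.05)
  expect_lt(rel_err(rep$esv_um3, sim$truth$esv_um3), 0.05)
  expect_lt(abs(rep$hr_bpm - 150), 3)
  expect_lt(rel_err(rep$co_nl_min, sim$truth$co_nl_min), 0.07)
})

test_that("a non-contracting heart reports zero function", {
  sim <- simulate_heart_video(tiny_heart(a_s = 120, b_s = 80, noise_sd = 0))
  rep <- cardiac_report(sim$video)
  expect_false(rep$contraction_detected)
  expect_true(is.na(rep$hr_bpm))
  expect_equal(rep$sv_um3, 0)
  expect_equal(rep$co_nl_min, 0)
  expect_equal(rep$sf_pct, 0)
  expect_equal(rep$ef_pct, 0)
  expect_equal(rep$fac_pct, 0)
})

test_that("pericardial edema area subtracts the ventricle", {
  frame <- matrix(0L, 120, 120)
  # rectangle polygon 100 x 50 px with a 40 x 50 ventricle inside
  poly <- cbind(c(10, 110, 110, 10), c(30, 30, 80, 80))
  vent <- matrix(FALSE, 120, 120); vent[41:80, 31:80] <- TRUE
  got <- pericardial_edema_area(frame, poly, vent, pixel_size = 1)
  expect_equal(got, 100 * 50 - 50 * 40)
  # ventricle filling the cavity -> zero edema
  full <- matrix(FALSE, 120, 120); full[31:80, 11:110] <- TRUE
  expect_equal(pericardial_edema_area(frame, poly, full, 1), 0)
  # annulus oracle: 64-gon of radius 40 around a disc of radius 20
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(60 + 40 * cos(ang), 60 + 40 * sin(ang))
  disc <- (row(frame) - 60.5)^2 + (col(frame) - 60.5)^2 <= 20^2
  expect_lt(rel_err(pericardial_edema_area(frame, circ, disc, 1),
                    pi * (40^2 - 20^2)), 0.01)
  # containment violation
  out <- matrix(FALSE, 120, 120); out[1:10, 1:10] <- TRUE
  expect_error(pericardial_edema_area(frame, poly, out, 1),
               class = "zfcardio_geometry")
})

test_that("landmark distances scale with the calibration", {
  expect_equal(linear_measure(c(0, 0), c(3, 4), 1), 5)
  expect_equal(linear_measure(c(2, 2), c(2, 2), 1), 0)
  expect_equal(linear_measure(c(0, 0), c(3, 4), 0.5), 2.5)
})
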