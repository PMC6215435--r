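# Synthetic microscopy generators with exactly known ground truth. They
# emulate the three live-imaging modalities the measurement chain targets:
# a beating-ventricle brightfield movie, erythrocyte flow in a vessel, and
# a confocal stack of a ring-shaped cerebral vessel structure.

#' Parameters for the beating-heart video generator
#'
#' The ventricle is modelled as a filled ellipse whose axes oscillate
#' between end-diastolic (`a_d`, `b_d`) and end-systolic (`a_s`, `b_s`)
#' extremes following a raised cosine,
#' `a(t) = a_s + (a_d - a_s) (1 + cos 2 pi f t)/2` with `f = heart_rate/60`,
#' so frame 1 (t = 0) is exactly end-diastole. Defaults reproduce a typical
#' 5 dpf acquisition: 150 fps for 10 s (~30 cardiac cycles at 180 bpm).
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param fps Frame rate in Hz.
#' @param duration Recording length in seconds.
#' @param heart_rate Beats per minute.
#' @param a_d,b_d Diastolic long/short axis in micrometres (`a_d >= b_d`).
#' @param a_s,b_s Systolic long/short axis in micrometres.
#' @param orientation Long-axis orientation in radians, in `[0, pi)`.
#' @param fg,bg Foreground (ventricle) and background intensity (8-bit).
#' @param noise_sd Additive Gaussian noise s.d. in intensity units;
#'   clipped to the 8-bit range.
#' @param seed RNG seed; identical seed and parameters give bit-identical
#'   output.
#' @param store_masks Keep the true per-frame binary masks in the ground
#'   truth (memory-heavy for long videos).
#' @return An object of class `heart_sim_params`.
#' @seealso [simulate_heart_video()]
#' @export
heart_sim_params <- function(width = 160, height = 160, pixel_size = 1,
                             fps = 150, duration = 10, heart_rate = 180,
                             a_d = 120, b_d = 80, a_s = 100, b_s = 60,
                             orientation = 0, fg = 200, bg = 30,
                             noise_sd = 8, seed = 1, store_masks = FALSE) {
  p <- as.list(environment())
  if (!(a_d >= b_d && b_d > 0 && a_s >= b_s && b_s > 0))
    zf_stop("bad_argument", "axes must satisfy a >= b > 0 at both extremes")
  if (!(a_d >= a_s && b_d >= b_s))
    zf_stop("bad_argument", "diastolic axes must be >= systolic axes")
  check_positive(heart_rate, "heart_rate")
  check_positive(fps, "fps"); check_positive(duration, "duration")
  check_positive(pixel_size, "pixel_size")
  if (fg <= bg) zf_stop("bad_argument", "fg intensity must exceed bg")
  structure(p, class = "heart_sim_params")
}

#' Simulate a beating-heart video with ground truth
#'
#' Renders the parametric ventricle of [heart_sim_params()] frame by frame
#' (a pixel is foreground iff its centre lies inside the ellipse), adds
#' clipped Gaussian noise, and returns the video together with the exact
#' per-frame axes and the analytic cardiac parameters. All derived ground
#' truth (EDV, ESV, SV, CO, SF, EF, FAC) is computed by the same formula
#' functions the measurement chain uses, e.g. [ellipsoid_volume()].
#'
#' @param params A [heart_sim_params()].
#' @return A list with elements `video` ([video_sequence()]) and `truth`
#'   (per-frame `a_um`, `b_um`, `area_um2`, analytic report values, and
#'   optionally the binary `masks`).
#' @examples
#' sim <- simulate_heart_video(heart_sim_params(duration = 0.5, fps = 60))
#' sim$video
#' sim$truth$edv_um3
#' @export
simulate_heart_video <- function(params) {
  stopifnot(inherits(params, "heart_sim_params"))
  p <- params
  T <- as.integer(round(p$fps * p$duration))
  if (T < 1L) zf_stop("bad_argument", "duration too short for one frame")
  tt <- (seq_len(T) - 1) / p$fps
  f <- p$heart_rate / 60
  osc <- (1 + cos(2 * pi * f * tt)) / 2
  a_t <- p$a_s + (p$a_d - p$a_s) * osc
  b_t <- p$b_s + (p$b_d - p$b_s) * osc

  # geometry check at maximal extent
  half_x <- ellipse_half_extent(p$a_d, p$b_d, p$orientation, "x") / p$pixel_size
  half_y <- ellipse_half_extent(p$a_d, p$b_d, p$orientation, "y") / p$pixel_size
  if (half_x > p$width / 2 - 1 || half_y > p$height / 2 - 1)
    zf_stop("geometry", "diastolic ellipse does not fit inside the frame")

  cx <- p$width / 2; cy <- p$height / 2
  xs <- (seq_len(p$width) - 0.5 - cx) * p$pixel_size
  ys <- (seq_len(p$height) - 0.5 - cy) * p$pixel_size
  ct <- cos(p$orientation); st <- sin(p$orientation)
  X <- matrix(xs, p$height, p$width, byrow = TRUE)
  Y <- matrix(ys, p$height, p$width)
  U <- X * ct + Y * st
  W <- -X * st + Y * ct

  # one outer-product pass renders all frames: a pixel is foreground iff
  # (u/(a/2))^2 + (w/(b/2))^2 <= 1 for that frame's axes
  Q <- outer(as.vector(U)^2, (2 / a_t)^2) + outer(as.vector(W)^2, (2 / b_t)^2)
  inside <- Q <= 1                               # (H*W, T)
  frames <- array(p$bg + (p$fg - p$bg) * aperm(
    array(inside, c(p$height, p$width, T)), c(3L, 1L, 2L)),
    c(T, p$height, p$width))
  masks <- if (isTRUE(p$store_masks))
    aperm(array(inside, c(p$height, p$width, T)), c(3L, 1L, 2L))
  frames <- add_clipped_noise(frames, p$noise_sd, p$seed)
  video <- video_sequence(frames, fps = p$fps, pixel_size = p$pixel_size)

  edv <- ellipsoid_volume(p$a_d, p$b_d)
  esv <- ellipsoid_volume(p$a_s, p$b_s)
  sv <- edv - esv
  area_d <- pi * p$a_d * p$b_d / 4
  area_s <- pi * p$a_s * p$b_s / 4
  truth <- list(
    time_s = tt, a_um = a_t, b_um = b_t, area_um2 = pi * a_t * b_t / 4,
    hr_bpm = p$heart_rate, n_cycles = f * p$duration,
    edv_um3 = edv, esv_um3 = esv, sv_um3 = sv,
    co_nl_min = p$heart_rate * sv / 1e6,
    sf_pct = (p$a_d - p$a_s) / p$a_d * 100,
    ef_pct = if (edv > 0) sv / edv * 100 else 0,
    fac_pct = (area_d - area_s) / area_d * 100,
    masks = masks)
  list(video = video, truth = truth)
}

#' Parameters for the erythrocyte-flow video generator
#'
#' Dark circular cells on a bright background are advected along +x at
#' constant velocity (`mode = "vein"`) or with a sinusoidal pulsatile
#' modulation `v(t) = v (1 + m sin 2 pi f_pulse t)` (`mode = "aorta"`);
#' `m < 1` keeps the instantaneous velocity non-negative. Cells leaving
#' the field re-enter at x = 0.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param fps Frame rate in Hz.
#' @param duration Recording length in seconds.
#' @param n_cells Number of erythrocytes.
#' @param velocity Mean advection velocity in micrometres per second.
#' @param mode `"vein"` (constant) or `"aorta"` (pulsatile).
#' @param pulsatility Modulation amplitude `m` in `[0, 1)` (aorta only).
#' @param pulse_freq Pulse frequency in Hz (aorta only).
#' @param cell_radius Cell radius in micrometres.
#' @param start_window Fraction of the field width over which initial
#'   cell positions are drawn (from x = 0). The default 1 spreads cells
#'   over the whole field; small values keep cells from wrapping during
#'   short recordings so that full-length tracks exist (aorta scoring).
#' @param fg,bg Cell and background intensity (cells darker).
#' @param noise_sd Additive Gaussian noise s.d., clipped to 8-bit range.
#' @param seed RNG seed.
#' @return An object of class `flow_sim_params`.
#' @export
flow_sim_params <- function(width = 256, height = 64, pixel_size = 0.5,
                            fps = 150, duration = 10, n_cells = 3,
                            velocity = 500, mode = c("vein", "aorta"),
                            pulsatility = 0.5, pulse_freq = 2.5,
                            cell_radius = 3, start_window = 1,
                            fg = 40, bg = 220, noise_sd = 8, seed = 1) {
  mode <- match.arg(mode)
  p <- c(as.list(environment()))
  if (start_window <= 0 || start_window > 1)
    zf_stop("bad_argument", "start_window must be in (0, 1]")
  if (velocity < 0) zf_stop("bad_argument", "velocity must be >= 0")
  if (mode == "aorta" && (pulsatility < 0 || pulsatility >= 1))
    zf_stop("bad_argument", "pulsatility must be in [0, 1)")
  if (n_cells < 1) zf_stop("bad_argument", "need at least one cell")
  if (cell_radius / pixel_size >= min(width, height) / 2)
    zf_stop("geometry", "cell radius must be smaller than the field")
  if (fg >= bg) zf_stop("bad_argument", "cells must be darker than background")
  structure(p, class = "flow_sim_params")
}

#' Simulate an erythrocyte-flow video with ground truth
#'
#' @param params A [flow_sim_params()].
#' @return A list with `video` and `truth`; the truth holds the exact
#'   sub-pixel position of every cell in every frame (`x_px`, `y_px`,
#'   frames x cells matrices), the per-cell time-averaged velocity and the
#'   nominal mean velocity.
#' @examples
#' sim <- simulate_flow_video(flow_sim_params(duration = 0.2))
#' dim(sim$truth$x_px)
#' @export
simulate_flow_video <- function(params) {
  stopifnot(inherits(params, "flow_sim_params"))
  p <- params
  T <- as.integer(round(p$fps * p$duration))
  if (T < 1L) zf_stop("bad_argument", "duration too short for one frame")
  tt <- (seq_len(T) - 1) / p$fps
  w_um <- p$width * p$pixel_size
  h_um <- p$height * p$pixel_size
  r_px <- p$cell_radius / p$pixel_size

  sim <- with_seed(p$seed, {
    # lateral positions: evenly spaced lanes with jitter, keeping cells
    # separated by more than a diameter so detections never merge
    lane <- h_um * (seq_len(p$n_cells) - 0.5) / p$n_cells
    jit <- runif(p$n_cells, -0.2, 0.2) * h_um / p$n_cells
    y0 <- pmin(pmax(lane + jit, p$cell_radius + p$pixel_size),
               h_um - p$cell_radius - p$pixel_size)
    x0 <- runif(p$n_cells, 0, w_um * p$start_window)
    list(y0 = y0, x0 = x0,
         noise_seed = sample.int(.Machine$integer.max, 1L))
  })

  disp <- if (p$mode == "vein") p$velocity * tt
  else p$velocity * tt + p$velocity * p$pulsatility *
    (1 - cos(2 * pi * p$pulse_freq * tt)) / (2 * pi * p$pulse_freq)
  x_um <- outer(disp, sim$x0, `+`) %% w_um      # T x n_cells
  y_um <- matrix(sim$y0, T, p$n_cells, byrow = TRUE)

  frames <- array(p$bg, c(T, p$height, p$width))
  for (k in seq_len(T)) {
    fr <- frames[k, , ]
    for (j in seq_len(p$n_cells)) {
      xc <- x_um[k, j] / p$pixel_size
      yc <- y_um[k, j] / p$pixel_size
      for (xw in xc + c(-p$width, 0, p$width))   # wrap-around rendering
        fr <- draw_disc(fr, xw, yc, r_px, p$fg)
    }
    frames[k, , ] <- fr
  }
  frames <- add_clipped_noise(frames, p$noise_sd, sim$noise_seed)
  video <- video_sequence(frames, fps = p$fps, pixel_size = p$pixel_size)

  # per-cell true mean velocity over the recorded window
  inst <- if (p$mode == "vein") rep(p$velocity, T)
  else p$velocity * (1 + p$pulsatility * sin(2 * pi * p$pulse_freq * tt))
  truth <- list(
    time_s = tt,
    x_px = x_um / p$pixel_size, y_px = y_um / p$pixel_size,
    x_um = x_um, y_um = y_um,
    v_inst = inst, mean_velocity = p$velocity, mode = p$mode)
  list(video = video, truth = truth)
}

#' Parameters for the ring-vessel stack generator
#'
#' A torus (centreline circle of radius `R` in an xy-plane, tube radius
#' `r`) stands in for the circular cerebral vessel structure; an optional
#' disconnected straight tube plays the role of an interfering vessel that
#' must be eliminated before volumetry. True ring volume is
#' `2 pi^2 R r^2`.
#'
#' @param nz,ny,nx Stack size in voxels (z, y, x).
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param R Centreline radius in micrometres.
#' @param r Tube radius in micrometres (`R > r > 0`).
#' @param include_interferer Add a disconnected straight tube along x.
#' @param interferer_radius Radius of the interfering tube (micrometres).
#' @param fg,bg Vessel and background intensity.
#' @param noise_sd Additive Gaussian noise s.d., clipped to 8-bit range.
#' @param seed RNG seed.
#' @return An object of class `vessel_sim_params`.
#' @export
vessel_sim_params <- function(nz = 24, ny = 240, nx = 240,
                              voxel_size = c(1, 0.5, 0.5),
                              R = 50, r = 5,
                              include_interferer = FALSE,
                              interferer_radius = 3,
                              fg = 220, bg = 20, noise_sd = 8, seed = 1) {
  p <- as.list(environment())
  if (!(R > r && r > 0)) zf_stop("bad_argument", "need R > r > 0")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    zf_stop("bad_argument", "voxel_size must be 3 positive numbers (dz, dy, dx)")
  structure(p, class = "vessel_sim_params")
}

#' Simulate a confocal-like ring-vessel stack with ground truth
#'
#' @param params A [vessel_sim_params()].
#' @return A list with `stack` ([voxel_stack()]) and `truth` (binary masks
#'   of ring and interferer, their voxel counts, the analytic ring volume
#'   `2 pi^2 R r^2`, and a voxel inside the ring usable as a seed point).
#' @examples
#' sim <- simulate_vessel_stack(vessel_sim_params(nz = 12, ny = 120, nx = 120,
#'                                                R = 20, r = 3))
#' sim$truth$ring_volume_um3
#' @export
simulate_vessel_stack <- function(params) {
  stopifnot(inherits(params, "vessel_sim_params"))
  p <- params
  dz <- p$voxel_size[1]; dy <- p$voxel_size[2]; dx <- p$voxel_size[3]
  zc <- p$nz * dz / 2
  yc <- p$ny * dy / 2
  xc <- p$nx * dx / 2
  if (2 * (p$R + p$r) > min(p$ny * dy, p$nx * dx) - 4 * max(dy, dx) ||
      2 * p$r > p$nz * dz - 4 * dz)
    zf_stop("geometry", "torus does not fit inside the stack")

  zv <- (seq_len(p$nz) - 0.5) * dz
  yv <- (seq_len(p$ny) - 0.5) * dy
  xv <- (seq_len(p$nx) - 0.5) * dx
  rho <- sqrt(outer((yv - yc)^2, (xv - xc)^2, `+`))    # ny x nx

  ring <- array(FALSE, c(p$nz, p$ny, p$nx))
  for (iz in seq_len(p$nz)) {
    s2 <- p$r^2 - (zv[iz] - zc)^2
    if (s2 > 0) ring[iz, , ] <- (rho - p$R)^2 <= s2
  }

  interferer <- NULL
  if (isTRUE(p$include_interferer)) {
    ri <- p$interferer_radius
    y0 <- ri + 2 * dy + 1e-9       # hugging the y = 0 edge of the field
    gap <- sqrt((yc - y0)^2) - (p$R + p$r) - ri
    if (y0 - ri < 0 || gap < 2 * max(dy, dx))
      zf_stop("geometry",
              "interferer does not fit disconnected from the ring; enlarge ny")
    interferer <- array(FALSE, c(p$nz, p$ny, p$nx))
    tube2 <- outer((zv - zc)^2, (yv - y0)^2, `+`) <= ri^2   # nz x ny
    xin <- xv >= 2 * dx & xv <= p$nx * dx - 2 * dx
    for (iz in seq_len(p$nz)) {
      if (any(tube2[iz, ]))
        interferer[iz, tube2[iz, ], xin] <- TRUE
    }
  }

  vox <- array(p$bg, c(p$nz, p$ny, p$nx))
  vox[ring] <- p$fg
  if (!is.null(interferer)) vox[interferer] <- p$fg
  vox <- add_clipped_noise(vox, p$noise_sd, p$seed)
  stack <- voxel_stack(vox, p$voxel_size)

  seed_idx <- which(ring, arr.ind = TRUE)[1, ]
  truth <- list(
    ring_mask = ring, interferer_mask = interferer,
    ring_voxels = sum(ring),
    interferer_voxels = if (is.null(interferer)) 0L else sum(interferer),
    ring_volume_um3 = 2 * pi^2 * p$R * p$r^2,
    voxel_volume_um3 = dz * dy * dx,
    seed_voxel = as.integer(seed_idx))
  list(stack = stack, truth = truth)
}

# ---- shared rendering helpers -------------------------------------------

# Half-extent of a rotated ellipse along image axis "x" or "y" (um).
ellipse_half_extent <- function(a, b, theta, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") sqrt((a / 2 * cos(theta))^2 + (b / 2 * sin(theta))^2)
  else sqrt((a / 2 * sin(theta))^2 + (b / 2 * cos(theta))^2)
}

# Paint a filled disc (pixel-centre rule) onto a matrix; silently clips at
# the border, which the callers use for wrap-around rendering.
draw_disc <- function(frame, cx, cy, r_px, value) {
  H <- nrow(frame); W <- ncol(frame)
  c0 <- max(1, floor(cx - r_px + 0.5)); c1 <- min(W, ceiling(cx + r_px + 0.5))
  r0 <- max(1, floor(cy - r_px + 0.5)); r1 <- min(H, ceiling(cy + r_px + 0.5))
  if (c1 < c0 || r1 < r0) return(frame)
  cs <- c0:c1
  rs <- r0:r1
  dx <- (cs - 0.5) - cx
  dy <- (rs - 0.5) - cy
  inside <- outer(dy^2, dx^2, `+`) <= r_px^2
  sub <- frame[rs, cs, drop = FALSE]
  sub[inside] <- value
  frame[rs, cs] <- sub
  frame
}

# Additive Gaussian noise, rounded and clipped to the 8-bit range.
add_clipped_noise <- function(arr, sd, seed) {
  d <- dim(arr)
  if (sd > 0) {
    x <- as.integer(round(arr + with_seed(seed, rnorm(length(arr), 0, sd))))
    x <- pmin.int(pmax.int(x, 0L), 255L)
  } else {
    x <- pmin.int(pmax.int(as.integer(round(arr)), 0L), 255L)
  }
  dim(x) <- d
  x
}
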