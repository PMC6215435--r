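# Small parameter sets used across tests: scaled-down acquisitions that
# keep the geometry of a 5 dpf larva (axes in um) but render quickly.

tiny_heart <- function(...) {
  defaults <- list(width = 72, height = 72, pixel_size = 2, fps = 50,
                   duration = 2, heart_rate = 150, noise_sd = 8, seed = 1)
  do.call(heart_sim_params, utils::modifyList(defaults, list(...)))
}

tiny_vein <- function(...) {
  defaults <- list(duration = 1, seed = 1)
  do.call(flow_sim_params, utils::modifyList(defaults, list(...)))
}

aorta_params <- function(...) {
  defaults <- list(width = 1900, height = 120, pixel_size = 1, fps = 50,
                   duration = 2, velocity = 800, mode = "aorta",
                   pulse_freq = 2.5, start_window = 0.04, seed = 1)
  do.call(flow_sim_params, utils::modifyList(defaults, list(...)))
}

tiny_torus <- function(...) {
  defaults <- list(nz = 12, ny = 120, nx = 120, voxel_size = c(1, 1, 1),
                   R = 30, r = 4, seed = 1)
  do.call(vessel_sim_params, utils::modifyList(defaults, list(...)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Construct a beat_series directly from an area trace (for beat-detection
# unit tests that bypass segmentation).
make_series <- function(area, fps, a = sqrt(area), b = sqrt(area)) {
  structure(list(frame = seq_along(area),
                 time_s = (seq_along(area) - 1) / fps,
                 area_um2 = area, a_um = a, b_um = b,
                 theta = rep(0, length(area)), fps = fps,
                 diastole = integer(0), systole = integer(0)),
            class = "beat_series")
}
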