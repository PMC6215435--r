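# Erythrocyte-tracking velocimetry: particle detection with sub-pixel
# centroids, greedy mutual-nearest-neighbour linking, and the vein /
# aorta scoring modes.

#' Particle-detection settings
#'
#' @param polarity Are cells darker (`"dark"`, brightfield erythrocytes)
#'   or brighter than the background?
#' @param threshold `"midpoint"` (default; halfway between the frame's
#'   median — the background level for sparse particles — and its
#'   maximum), `"otsu"`, or a numeric intensity cutoff. Otsu assumes a
#'   sizeable foreground class and over-segments frames that are almost
#'   entirely background, so midpoint is the robust default here.
#' @param radius_range Admissible particle radius range in pixels; blobs
#'   with pixel counts outside `pi * r^2` of this range are discarded.
#'   Blobs touching the image border are always discarded (their
#'   centroids are biased).
#' @return A list of class `particle_settings`.
#' @export
particle_settings <- function(polarity = c("dark", "bright"),
                              threshold = "midpoint",
                              radius_range = c(1, 12)) {
  polarity <- match.arg(polarity)
  if (!identical(threshold, "otsu") && !identical(threshold, "midpoint") &&
      !is.numeric(threshold))
    zf_stop("bad_argument",
            "threshold must be \"midpoint\", \"otsu\" or numeric")
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    zf_stop("bad_argument", "radius_range must be increasing and positive")
  structure(list(polarity = polarity, threshold = threshold,
                 radius_range = radius_range), class = "particle_settings")
}

# Batched particle detection over a (T, H, W) array. Returns a list of
# T matrices with columns x, y (sub-pixel, intensity-weighted centroids)
# and n (blob pixel count).
detect_particles_stack <- function(frames, settings) {
  d <- dim(frames); T <- d[1]; H <- d[2]; W <- d[3]
  maxv <- if (max(frames) > 255L) 65535 else 255
  work <- if (settings$polarity == "dark") maxv - frames else frames
  th <- if (is.numeric(settings$threshold)) {
    rep(settings$threshold, T)
  } else if (identical(settings$threshold, "midpoint")) {
    cnt <- frame_histograms(work, maxv)
    cum <- t(apply(cnt, 1, cumsum))
    half <- cum[, maxv + 1L] / 2
    med <- max.col(cum >= half, ties.method = "first") - 1L
    mx <- (maxv + 1L) - max.col(cnt[, (maxv + 1L):1, drop = FALSE] > 0,
                                ties.method = "first")
    (med + mx) / 2
  } else {
    otsu_thresholds(frame_histograms(work, maxv))
  }
  bw <- work > th[rep_len(seq_len(T), length(work))]
  dim(bw) <- d
  bw <- aperm(bw, c(2L, 3L, 1L))
  lab <- as.array(EBImage::bwlabel(bw))

  empty <- replicate(T, cbind(x = numeric(0), y = numeric(0), n = numeric(0)),
                     simplify = FALSE)
  idx <- which(lab > 0L)
  if (!length(idx)) return(empty)
  labv <- as.integer(lab[idx])
  si <- idx - 1L
  h <- si %% H + 1L
  w <- (si %/% H) %% W + 1L
  fr <- si %/% (H * W) + 1L
  nlab <- max(labv)
  key <- (fr - 1L) * nlab + labv
  cnt <- tabulate(key, T * nlab)
  amin <- pi * settings$radius_range[1]^2
  amax <- pi * settings$radius_range[2]^2
  okkey <- which(cnt >= amin & cnt <= amax)
  # drop blobs touching the field border: their centroids are biased
  # toward the visible fragment
  border <- h == 1L | h == H | w == 1L | w == W
  if (any(border)) {
    btab <- tabulate(key[border], length(cnt))
    okkey <- okkey[btab[okkey] == 0L]
  }
  keep <- key %in% okkey
  if (!any(keep)) return(empty)

  # intensity-weighted centroid: weight = signal above threshold
  wgt <- pmax(work[cbind(fr, h, w)[keep, , drop = FALSE]] - th[fr[keep]],
              1e-9)
  x <- w[keep] - 0.5; y <- h[keep] - 0.5
  g <- match(key[keep], okkey)
  m <- rowsum(cbind(wgt, wgt * x, wgt * y), g, reorder = FALSE)
  ug <- okkey[as.integer(rownames(m))]
  det <- cbind(frame = (ug - 1L) %/% nlab + 1L,
               x = m[, 2] / m[, 1], y = m[, 3] / m[, 1],
               n = cnt[ug])
  out <- empty
  for (f in unique(det[, "frame"])) {
    rows <- det[det[, "frame"] == f, , drop = FALSE]
    out[[f]] <- rows[order(rows[, "x"]), c("x", "y", "n"), drop = FALSE]
  }
  out
}

#' Detect particle-like cells in a single frame
#'
#' Thresholds the frame (Otsu by default, honouring polarity), labels
#' connected blobs, discards blobs outside the admissible radius range,
#' and returns intensity-weighted sub-pixel centroids.
#'
#' @param frame 2D integer intensity matrix.
#' @param settings A [particle_settings()].
#' @return A matrix with columns `x`, `y` (pixel coordinates) and `n`
#'   (blob pixel count); zero rows when nothing is detected.
#' @export
detect_particles <- function(frame, settings = particle_settings()) {
  if (!is.matrix(frame)) zf_stop("bad_argument", "frame must be a matrix")
  detect_particles_stack(array(as.integer(frame), c(1L, dim(frame))),
                         settings)[[1]]
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking from frame `t` to `t + 1`:
#' a detection extends a track only when each is the other's nearest
#' neighbour within `max_disp`; among mutual pairs, smaller displacements
#' are linked first, which resolves crossing ambiguities in favour of the
#' smallest total displacement. Unmatched detections start new tracks;
#' a track that misses a frame is closed (frame indices within a track
#' are strictly consecutive).
#'
#' @param detections List (one element per frame) of detection matrices
#'   as returned by [detect_particles()].
#' @param max_disp Maximum per-frame displacement in pixels.
#' @return A list of tracks (class `track_set`); each track is a data
#'   frame with `frame`, `x`, `y` plus an `id` attribute. Tracks shorter
#'   than 2 frames are dropped.
#' @export
link_tracks <- function(detections, max_disp) {
  check_positive(max_disp, "max_disp")
  T <- length(detections)
  active <- list()   # each: list(rows = data.frame(frame, x, y))
  done <- list()
  d1 <- detections[[1]]
  for (r in seq_len(nrow(d1)))
    active[[length(active) + 1L]] <-
      data.frame(frame = 1L, x = d1[r, "x"], y = d1[r, "y"])
  for (t in seq_len(T - 1L)) {
    B <- detections[[t + 1L]]
    nA <- length(active); nB <- nrow(B)
    matched_a <- integer(0); matched_b <- integer(0)
    if (nA > 0L && nB > 0L) {
      ax <- vapply(active, function(tr) tr$x[nrow(tr)], numeric(1))
      ay <- vapply(active, function(tr) tr$y[nrow(tr)], numeric(1))
      D <- sqrt(outer(ax, B[, "x"], `-`)^2 + outer(ay, B[, "y"], `-`)^2)
      na_min <- apply(D, 1, which.min)
      nb_min <- apply(D, 2, which.min)
      mutual <- which(nb_min[na_min] == seq_len(nA) &
                        D[cbind(seq_len(nA), na_min)] <= max_disp)
      ord <- mutual[order(D[cbind(mutual, na_min[mutual])])]
      for (i in ord) {
        j <- na_min[i]
        if (i %in% matched_a || j %in% matched_b) next
        matched_a <- c(matched_a, i); matched_b <- c(matched_b, j)
        active[[i]] <- rbind(active[[i]],
                             data.frame(frame = t + 1L,
                                        x = B[j, "x"], y = B[j, "y"]))
      }
    }
    # close tracks that were not extended
    stale <- setdiff(seq_len(nA), matched_a)
    done <- c(done, active[stale])
    active <- active[matched_a[order(matched_a)]]
    for (j in setdiff(seq_len(nB), matched_b))
      active[[length(active) + 1L]] <-
        data.frame(frame = t + 1L, x = B[j, "x"], y = B[j, "y"])
  }
  tracks <- c(done, active)
  tracks <- tracks[vapply(tracks, nrow, integer(1)) >= 2L]
  tracks <- tracks[order(vapply(tracks, function(tr) tr$frame[1], integer(1)))]
  for (i in seq_along(tracks)) attr(tracks[[i]], "id") <- i
  structure(tracks, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  lens <- vapply(x, nrow, integer(1))
  cat(sprintf("%d tracks; lengths %s\n", length(x),
              paste(sort(lens, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Mean velocity of one track
#'
#' Mean frame-to-frame displacement magnitude over the first `n_frames`
#' positions of the track, converted to micrometres per second.
#'
#' @param track One track from [link_tracks()].
#' @param fps Frame rate in Hz.
#' @param pixel_size Micrometres per pixel.
#' @param n_frames Number of positions scored (default 10, the classical
#'   ten-frame window); `NULL` scores the whole track.
#' @return Velocity in micrometres per second.
#' @export
track_velocity <- function(track, fps, pixel_size, n_frames = 10) {
  check_positive(fps, "fps"); check_positive(pixel_size, "pixel_size")
  if (is.null(n_frames)) n_frames <- nrow(track)
  if (nrow(track) < n_frames)
    zf_stop("insufficient_track", "track has %d < %d frames",
            nrow(track), n_frames)
  xy <- as.matrix(track[seq_len(n_frames), c("x", "y")])
  steps <- sqrt(rowSums(diff(xy)^2))
  mean(steps) * pixel_size * fps
}

#' Blood-flow velocity report from a video
#'
#' Detects erythrocyte-like particles in every frame, links them into
#' tracks, and scores the three longest tracks. In `"vein"` mode each
#' cell is scored over its first ten frames (venous flow is steady, so a
#' short window suffices). In `"aorta"` mode each cell is averaged over
#' its entire track so that pulsatile phases cancel; tracks must span at
#' least 80 percent of the recording.
#'
#' @param video A [video_sequence()].
#' @param mode `"vein"` or `"aorta"`.
#' @param settings A [particle_settings()].
#' @param max_disp Maximum per-frame displacement in pixels (must exceed
#'   the expected displacement `v / (fps * pixel_size)`).
#' @param n_frames Frames per scoring window in vein mode.
#' @return A `velocity_report`: `mode`, per-cell table `cells`,
#'   `mean_velocity` (arithmetic mean over cells, um/s), `n_cells`,
#'   `frames_used`.
#' @export
flow_report <- function(video, mode = c("vein", "aorta"),
                        settings = particle_settings(), max_disp = 15,
                        n_frames = 10) {
  stopifnot(inherits(video, "video_sequence"))
  mode <- match.arg(mode)
  det <- detect_particles_stack(video$frames, settings)
  tracks <- link_tracks(det, max_disp)
  T <- n_frames(video)
  lens <- vapply(tracks, nrow, integer(1))
  min_len <- if (mode == "vein") n_frames else ceiling(0.8 * T)
  usable <- which(lens >= min_len)
  if (length(usable) < 3L)
    zf_stop("insufficient_cells",
            "only %d trackable cells with >= %d frames (need 3)",
            length(usable), min_len)
  sel <- usable[order(lens[usable], decreasing = TRUE)][1:3]
  win <- if (mode == "vein") n_frames else NULL
  v <- vapply(sel, function(i)
    track_velocity(tracks[[i]], video$fps, video$pixel_size, win),
    numeric(1))
  frames_used <- if (mode == "vein") rep(n_frames, 3L) else lens[sel]
  structure(list(
    mode = mode,
    cells = data.frame(track = sel, track_length = lens[sel],
                       frames_scored = frames_used, velocity_um_s = v),
    mean_velocity = mean(v), n_cells = 3L,
    frames_used = frames_used, n_tracks_total = length(tracks)),
    class = "velocity_report")
}

#' @export
print.velocity_report <- function(x, ...) {
  cat(sprintf("Blood-flow velocity (%s mode): %.1f um/s over %d cells\n",
              x$mode, x$mean_velocity, x$n_cells))
  cat(sprintf("  per-cell: %s um/s\n",
              paste(sprintf("%.1f", x$cells$velocity_um_s), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.velocity_report <- function(x, ...) {
  data.frame(mode = x$mode, n_cells = x$n_cells,
             mean_velocity_um_s = x$mean_velocity,
             min_frames_scored = min(x$frames_used))
}
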