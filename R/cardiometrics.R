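# Cardiac function from high-speed video: per-frame ventricle
# segmentation, equal-moments ellipse fit, beat detection on the area
# trace, and the classical ellipsoid-model cardiac parameters.

#' Segmentation settings for the ventricle / particle detectors
#'
#' @param polarity Is the object brighter (`"bright"`) or darker
#'   (`"dark"`) than the background?
#' @param threshold `"otsu"` for Otsu's global threshold computed per
#'   frame, or a numeric intensity cutoff (object side inclusive-exclusive
#'   as `> threshold` after polarity normalisation).
#' @param fill_holes Fill enclosed holes in the segmented object.
#' @return A list of class `seg_settings`.
#' @export
seg_settings <- function(polarity = c("bright", "dark"), threshold = "otsu",
                         fill_holes = TRUE) {
  polarity <- match.arg(polarity)
  if (!identical(threshold, "otsu") && !is.numeric(threshold))
    zf_stop("bad_argument", "threshold must be \"otsu\" or numeric")
  structure(list(polarity = polarity, threshold = threshold,
                 fill_holes = fill_holes), class = "seg_settings")
}

# Per-frame intensity histograms of a (T, H, W) integer array, as a
# (maxv + 1) x T count matrix, in one tabulate pass (time is the fastest
# varying dimension, so the frame index of every voxel is rep_len(1:T)).
frame_histograms <- function(work, maxv) {
  T <- dim(work)[1]
  fr <- rep_len(seq_len(T), length(work))
  matrix(tabulate(as.vector(work) * T + fr, (maxv + 1L) * T),
         nrow = T, ncol = maxv + 1L)          # [t, v + 1]
}

# Otsu's threshold per frame from the histogram matrix: the intensity k
# maximising the between-class variance of the split (<= k) vs (> k).
otsu_thresholds <- function(cnt) {
  T <- nrow(cnt); K <- ncol(cnt)
  v <- 0:(K - 1L)
  th <- numeric(T)
  for (t in seq_len(T)) {
    w0 <- cumsum(as.numeric(cnt[t, ]))
    mu0 <- cumsum(as.numeric(cnt[t, ]) * v)
    N <- w0[K]; muT <- mu0[K]
    valid <- w0 > 0 & w0 < N
    if (!any(valid)) {        # uniform frame: nothing separable
      th[t] <- v[K]
      next
    }
    sb <- rep(-Inf, K)
    sb[valid] <- (muT * w0[valid] - N * mu0[valid])^2 /
      (w0[valid] * (N - w0[valid]))
    th[t] <- v[which.max(sb)]
  }
  th
}

# Batched segmentation of a (T, H, W) integer array: global threshold per
# frame (Otsu by default), per-frame connected-component labelling with
# hole filling (EBImage), selection of the largest component, and central
# image moments of the selected component -- all vectorised across frames.
# Returns per-frame moment summaries plus the label volume for callers
# that need masks.
segment_stack <- function(frames, settings) {
  d <- dim(frames)
  T <- d[1]; H <- d[2]; W <- d[3]
  maxv <- if (max(frames) > 255L) 65535 else 255
  work <- if (settings$polarity == "dark") maxv - frames else frames
  th <- if (is.numeric(settings$threshold)) rep(settings$threshold, T)
  else otsu_thresholds(frame_histograms(work, maxv))
  bw <- work > th[rep_len(seq_len(T), length(work))]
  dim(bw) <- d
  bw <- aperm(bw, c(2L, 3L, 1L))                  # (H, W, T) for EBImage
  lab <- EBImage::bwlabel(bw)
  if (isTRUE(settings$fill_holes)) lab <- EBImage::fillHull(lab)
  lab <- as.array(lab)

  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    zf_stop("no_object", "no foreground pixels in any frame")
  labv <- as.integer(lab[idx])
  fr <- (idx - 1L) %/% (H * W) + 1L
  nlab <- max(labv)
  cnt <- matrix(tabulate((fr - 1L) * nlab + labv, T * nlab), nlab, T)
  empty <- which(colSums(cnt) == 0L)
  if (length(empty))
    zf_stop("no_object", "no foreground pixels in frame %d", empty[1])
  best <- max.col(t(cnt), ties.method = "first")   # largest label per frame

  keep <- labv == best[fr]
  si <- idx[keep] - 1L
  h <- si %% H + 1L
  w <- (si %/% H) %% W + 1L
  t <- si %/% (H * W) + 1L
  x <- w - 0.5
  y <- h - 0.5
  m <- unname(rowsum(cbind(1, x, y, x * x, y * y, x * y), t, reorder = TRUE))
  n <- m[, 1]
  mx <- m[, 2] / n; my <- m[, 3] / n
  list(n = n, cx = mx, cy = my,
       cxx = m[, 4] / n - mx^2, cyy = m[, 5] / n - my^2,
       cxy = m[, 6] / n - mx * my,
       threshold = th, labels = lab, best = best)
}

#' Segment the ventricle (largest object) in a single frame
#'
#' Applies a global threshold (Otsu over the frame's histogram by
#' default), fills enclosed holes, and keeps the largest connected
#' foreground component. This automates the manual perimeter outlining of
#' the classical workflow.
#'
#' @param frame 2D integer intensity matrix (one video frame).
#' @param settings A [seg_settings()].
#' @return A `region_mask`: list with the logical `mask`, `pixel_count`,
#'   `bbox` (`rmin, rmax, cmin, cmax`) and the `threshold` used.
#' @seealso [fit_ellipse()], [area_series()]
#' @export
segment_ventricle <- function(frame, settings = seg_settings()) {
  if (!is.matrix(frame)) zf_stop("bad_argument", "frame must be a matrix")
  st <- segment_stack(array(as.integer(frame), c(1L, dim(frame))), settings)
  mask <- st$labels[, , 1] == st$best[1]
  rc <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask, pixel_count = nrow(rc),
                 bbox = c(rmin = min(rc[, 1]), rmax = max(rc[, 1]),
                          cmin = min(rc[, 2]), cmax = max(rc[, 2])),
                 threshold = st$threshold[1]),
            class = "region_mask")
}

#' Fit the equal-moments ellipse to a binary region
#'
#' The fitted ellipse shares the region's centroid and second central
#' moments ("fit to ellipse" in the classical sense): with eigenvalues
#' `l1 >= l2` of the pixel-coordinate covariance, the axes are
#' `a = 4 sqrt(l1)`, `b = 4 sqrt(l2)` (in calibrated micrometres), which
#' makes the ellipse area `pi a b / 4` match the mask area in the
#' continuum limit. Orientation is the leading eigenvector direction in
#' `[0, pi)`, reported as 0 for rotationally symmetric regions.
#'
#' @param mask A `region_mask` from [segment_ventricle()] or a logical
#'   matrix.
#' @param pixel_size Micrometres per pixel.
#' @return An `ellipse_fit`: list with `centre` (x, y in px), `a`, `b`
#'   (micrometres), `theta` (radians) and `pixel_count`.
#' @examples
#' m <- outer(1:101, 1:101, function(r, c) (r - 51)^2 + (c - 51)^2 <= 50^2)
#' fit_ellipse(m, pixel_size = 1)
#' @export
fit_ellipse <- function(mask, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  if (inherits(mask, "region_mask")) mask <- mask$mask
  rc <- which(mask, arr.ind = TRUE)
  n <- nrow(rc)
  if (n < 5L) zf_stop("degenerate_region", "mask has fewer than 5 pixels")
  x <- rc[, 2] - 0.5
  y <- rc[, 1] - 0.5
  mx <- mean(x); my <- mean(y)
  e <- eigen2x2(mean(x^2) - mx^2, mean(y^2) - my^2, mean(x * y) - mx * my)
  if (e$l2 <= 1e-9)
    zf_stop("degenerate_region", "collinear mask pixels; no ellipse defined")
  a <- 4 * sqrt(e$l1) * pixel_size
  b <- 4 * sqrt(e$l2) * pixel_size
  theta <- if ((e$l1 - e$l2) / e$l1 < 1e-3) 0 else e$theta
  structure(list(centre = c(x = mx, y = my), a = a, b = b, theta = theta,
                 pixel_count = n),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "Equal-moments ellipse: a = %.2f um, b = %.2f um, theta = %.1f deg\n",
    x$a, x$b, x$theta * 180 / pi))
  cat(sprintf("  centre (%.2f, %.2f) px from %d pixels\n",
              x$centre[1], x$centre[2], x$pixel_count))
  invisible(x)
}

#' Per-frame ventricular area and axis series
#'
#' Segments the ventricle and fits the equal-moments ellipse in every
#' frame (vectorised across the whole video), yielding the calibrated
#' area/axis traces on which beats are detected.
#'
#' @param video A [video_sequence()].
#' @param settings A [seg_settings()].
#' @return A `beat_series`: list with per-frame `frame`, `time_s`,
#'   `area_um2`, `a_um`, `b_um`, `theta`, the `fps`, and (initially empty)
#'   `diastole` / `systole` frame indices.
#' @seealso [detect_beats()], [cardiac_report()]
#' @export
area_series <- function(video, settings = seg_settings()) {
  stopifnot(inherits(video, "video_sequence"))
  st <- segment_stack(video$frames, settings)
  ps <- video$pixel_size
  e <- eigen2x2(st$cxx, st$cyy, st$cxy)
  if (any(e$l2 <= 1e-9))
    zf_stop("degenerate_region", "degenerate ventricle mask in frame %d",
            which(e$l2 <= 1e-9)[1])
  structure(list(
    frame = seq_along(st$n),
    time_s = (seq_along(st$n) - 1) / video$fps,
    area_um2 = st$n * ps^2,
    a_um = 4 * sqrt(e$l1) * ps,
    b_um = 4 * sqrt(e$l2) * ps,
    theta = ifelse((e$l1 - e$l2) / e$l1 < 1e-3, 0, e$theta),
    fps = video$fps,
    diastole = integer(0), systole = integer(0)),
    class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("Ventricular series: %d frames at %g fps (%.2f s)\n",
              length(x$frame), x$fps, length(x$frame) / x$fps))
  cat(sprintf("  area %.0f-%.0f um^2, long axis %.1f-%.1f um\n",
              min(x$area_um2), max(x$area_um2), min(x$a_um), max(x$a_um)))
  if (length(x$diastole))
    cat(sprintf("  %d diastoles, %d systoles detected\n",
                length(x$diastole), length(x$systole)))
  invisible(x)
}

#' @export
plot.beat_series <- function(x, ...) {
  plot(x$time_s, x$area_um2, type = "l", xlab = "time (s)",
       ylab = expression(paste("ventricular area (", mu, m^2, ")")), ...)
  if (length(x$diastole)) {
    points(x$time_s[x$diastole], x$area_um2[x$diastole], col = 2, pch = 19)
    points(x$time_s[x$systole], x$area_um2[x$systole], col = 4, pch = 19)
    legend("topright", c("diastole", "systole"), col = c(2, 4), pch = 19,
           bty = "n")
  }
  invisible(x)
}

#' Detect diastole and systole on the ventricular area trace
#'
#' The area series is smoothed with a short moving average
#' (`round(fps / 10)` frames), the dominant beat period is taken from the
#' first autocorrelation peak, and diastoles are local maxima separated by
#' at least 0.4 dominant periods. Systoles are the area minima between
#' consecutive diastoles, which enforces strict alternation. At least
#' three complete diastole-systole-diastole beats are required.
#'
#' @param series A `beat_series` from [area_series()].
#' @param fps Frame rate in Hz (defaults to the series' own).
#' @return The series with `diastole` and `systole` frame indices set.
#' @export
detect_beats <- function(series, fps = series$fps) {
  stopifnot(inherits(series, "beat_series"))
  a <- series$area_um2
  n <- length(a)
  if (n < 2 * fps)
    zf_stop("no_beat", "series shorter than 2 s (%d frames at %g fps)", n, fps)
  rng <- max(a) - min(a)
  if (rng < 1e-3 * max(a))
    zf_stop("no_beat", "flat area series; no contraction detected")
  s <- moving_average(a, round(fps / 10))

  ac <- acf(s - mean(s), lag.max = floor(n / 2), plot = FALSE,
            demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  cand <- which(diff(sign(diff(ac))) < 0) + 1L     # local maxima of the acf
  cand <- cand[lags[cand] >= 2L]
  if (!length(cand) || max(ac[cand]) < 0.2)
    zf_stop("no_beat", "no dominant cardiac period in the area series")
  period <- lags[cand[which.max(ac[cand])]]
  minsep <- max(1, 0.4 * period)

  dia <- find_peaks(s, minsep)
  if (length(dia) < 4L)
    zf_stop("no_beat", "fewer than 3 complete beats (%d diastoles)",
            length(dia))
  sys <- vapply(seq_len(length(dia) - 1L), function(i) {
    span <- (dia[i] + 1L):(dia[i + 1L] - 1L)
    span[which.min(s[span])]
  }, integer(1))
  series$diastole <- dia
  series$systole <- sys
  series
}

# Local maxima with a minimum separation, kept greedily by height.
# The first sample counts as a peak when the series falls away from it
# (recordings conventionally start at end-diastole); the last sample
# never does, because a rising endpoint's true peak lies beyond the
# recording.
find_peaks <- function(s, minsep) {
  n <- length(s)
  left <- c(TRUE, s[-1] > s[-n])
  right <- c(s[-n] >= s[-1], TRUE)
  cand <- setdiff(which(left & right), n)
  cand <- cand[order(s[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(kept - i) >= minsep)) kept <- c(kept, i)
  sort(kept)
}

#' Heart rate from detected diastoles
#'
#' The heart rate is measured over the time interval spanning three
#' heartbeats: `HR = 3 * 60 / dt` where `dt` is the time from the first
#' diastole to the fourth.
#'
#' @param series A `beat_series` with beats detected.
#' @param fps Frame rate in Hz.
#' @return Heart rate in beats per minute.
#' @export
heart_rate <- function(series, fps = series$fps) {
  d <- series$diastole
  if (length(d) < 4L)
    zf_stop("no_beat", "need at least 4 diastoles to span 3 beats")
  dt <- (d[4] - d[1]) / fps
  3 * 60 / dt
}

#' Ventricular volume from the prolate-spheroid model
#'
#' `V = (4/3) pi (b/2)^2 (a/2)`: the ventricle is treated as a spheroid
#' with the fitted long axis `a` and the short axis `b` as both transverse
#' diameters (short axis enters squared).
#'
#' @param a Long axis in micrometres (`a >= b`), vectorised.
#' @param b Short axis in micrometres.
#' @return Volume(s) in cubic micrometres.
#' @examples
#' ellipsoid_volume(120, 80)   # 402123.9 um^3
#' @export
ellipsoid_volume <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(b <= 0) || any(a < b))
    zf_stop("bad_argument", "axes must satisfy a >= b > 0")
  (4 / 3) * pi * (b / 2)^2 * (a / 2)
}

#' Full cardiac-function report from a high-speed video
#'
#' Runs the complete measurement chain: per-frame segmentation and ellipse
#' fitting ([area_series()]), beat detection ([detect_beats()]), heart
#' rate over three beats ([heart_rate()]), and the cardiac parameters
#' averaged over the first three complete beats ("in triplicate"):
#' per-beat EDV and ESV from [ellipsoid_volume()] at the diastolic and
#' systolic frames, `SV = mean(EDV_i - ESV_i)`, `CO = HR x SV`,
#' `SF = (a_dia - a_sys)/a_dia x 100` from the fitted long axes,
#' `EF = SV/EDV x 100`, and `FAC = (area_dia - area_sys)/area_dia x 100`.
#'
#' A video with no detectable contraction (flat area trace) yields a
#' report with zero stroke volume, output and fractions and `hr_bpm = NA`.
#'
#' @param video A [video_sequence()].
#' @param settings A [seg_settings()].
#' @return A `cardiac_report` with `hr_bpm`; `edv_um3`, `esv_um3`,
#'   `sv_um3` (and `_nl` twins, 1 nL = 1e6 um^3); `co_nl_min`; `sf_pct`,
#'   `ef_pct`, `fac_pct`; a per-beat table `beats`; and `n_beats_used`.
#' @export
cardiac_report <- function(video, settings = seg_settings()) {
  series <- area_series(video, settings)
  rng <- max(series$area_um2) - min(series$area_um2)
  if (rng < 1e-3 * max(series$area_um2)) {
    a_bar <- mean(series$a_um); b_bar <- mean(series$b_um)
    v <- ellipsoid_volume(a_bar, b_bar)
    return(new_cardiac_report(
      hr_bpm = NA_real_, edv = v, esv = v, sv = 0, co = 0,
      sf = 0, ef = 0, fac = 0,
      beats = data.frame(beat = integer(0), diastole_frame = integer(0),
                         systole_frame = integer(0), edv_um3 = numeric(0),
                         esv_um3 = numeric(0)),
      contraction = FALSE, series = series))
  }
  series <- detect_beats(series)
  hr <- heart_rate(series)
  d <- series$diastole[1:3]
  s <- series$systole[1:3]
  edv_i <- ellipsoid_volume(series$a_um[d], series$b_um[d])
  esv_i <- ellipsoid_volume(series$a_um[s], series$b_um[s])
  edv <- mean(edv_i); esv <- mean(esv_i)
  if (esv > edv)
    zf_stop("inconsistent", "mean ESV exceeds mean EDV; check segmentation")
  sv <- mean(edv_i - esv_i)
  a_dia <- mean(series$a_um[d]); a_sys <- mean(series$a_um[s])
  ar_dia <- mean(series$area_um2[d]); ar_sys <- mean(series$area_um2[s])
  new_cardiac_report(
    hr_bpm = hr, edv = edv, esv = esv, sv = sv,
    co = hr * sv / 1e6,
    sf = (a_dia - a_sys) / a_dia * 100,
    ef = sv / edv * 100,
    fac = (ar_dia - ar_sys) / ar_dia * 100,
    beats = data.frame(beat = 1:3, diastole_frame = d, systole_frame = s,
                       edv_um3 = edv_i, esv_um3 = esv_i),
    contraction = TRUE, series = series)
}

new_cardiac_report <- function(hr_bpm, edv, esv, sv, co, sf, ef, fac, beats,
                               contraction, series) {
  structure(list(
    hr_bpm = hr_bpm,
    edv_um3 = edv, esv_um3 = esv, sv_um3 = sv,
    edv_nl = edv / 1e6, esv_nl = esv / 1e6, sv_nl = sv / 1e6,
    co_nl_min = co,
    sf_pct = sf, ef_pct = ef, fac_pct = fac,
    beats = beats, n_beats_used = nrow(beats),
    contraction_detected = contraction, series = series),
    class = "cardiac_report")
}

#' @export
print.cardiac_report <- function(x, ...) {
  cat("Cardiac function report (triplicate beats)\n")
  cat(sprintf("  heart rate          : %s bpm\n",
              if (is.na(x$hr_bpm)) "NA (no contraction)"
              else sprintf("%.1f", x$hr_bpm)))
  cat(sprintf("  EDV / ESV           : %.0f / %.0f um^3 (%.4f / %.4f nL)\n",
              x$edv_um3, x$esv_um3, x$edv_nl, x$esv_nl))
  cat(sprintf("  stroke volume       : %.0f um^3 (%.4f nL)\n",
              x$sv_um3, x$sv_nl))
  cat(sprintf("  cardiac output      : %.3f nL/min\n", x$co_nl_min))
  cat(sprintf("  SF / EF / FAC       : %.1f%% / %.1f%% / %.1f%%\n",
              x$sf_pct, x$ef_pct, x$fac_pct))
  invisible(x)
}

#' @export
summary.cardiac_report <- function(object, ...) {
  print(object)
  if (nrow(object$beats)) {
    cat("  per-beat volumes (um^3):\n")
    print(object$beats, row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.cardiac_report <- function(x, ...) {
  data.frame(hr_bpm = x$hr_bpm, edv = x$edv_um3, esv = x$esv_um3,
             sv = x$sv_um3, co = x$co_nl_min, sf_pct = x$sf_pct,
             ef_pct = x$ef_pct, fac_pct = x$fac_pct)
}

#' Pericardial edema area
#'
#' Area of the pericardial cavity minus the ventricular area, correcting
#' for possibly enlarged ventricles. The pericardial outline is supplied
#' as landmark polygon coordinates (landmark placement is not automated);
#' it is rasterised with the same pixel-centre rule as the masks.
#'
#' @param frame 2D intensity matrix (used for the raster extent only).
#' @param pericardial_outline `n x 2` matrix of polygon vertices
#'   `(x, y)` in pixel coordinates.
#' @param ventricle_mask A `region_mask` or logical matrix; must lie
#'   inside the polygon.
#' @param pixel_size Micrometres per pixel.
#' @return Edema area in square micrometres.
#' @export
pericardial_edema_area <- function(frame, pericardial_outline, ventricle_mask,
                                   pixel_size) {
  check_positive(pixel_size, "pixel_size")
  if (inherits(ventricle_mask, "region_mask"))
    ventricle_mask <- ventricle_mask$mask
  H <- nrow(frame); W <- ncol(frame)
  bnd <- as.matrix(pericardial_outline)
  if (!all(bnd[1, ] == bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
  px <- cbind(rep(seq_len(W) - 0.5, each = H),
              rep(seq_len(H) - 0.5, times = W))
  inside <- matrix(mgcv::in.out(bnd, px), H, W)
  if (any(ventricle_mask & !inside))
    zf_stop("geometry", "ventricle mask is not contained in the outline")
  (sum(inside) - sum(ventricle_mask)) * pixel_size^2
}

#' Calibrated distance between two landmarks
#'
#' Euclidean distance between two points (e.g. interorbital distance or
#' body length landmarks) scaled by the pixel size.
#'
#' @param p1,p2 Numeric length-2 points `(x, y)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @return Distance in micrometres.
#' @examples
#' linear_measure(c(0, 0), c(3, 4), pixel_size = 1)  # 5
#' @export
linear_measure <- function(p1, p2, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) * pixel_size
}
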