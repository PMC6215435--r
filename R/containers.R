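#' Calibration metadata for microscopy acquisitions
#'
#' Bundles the acquisition calibration that every quantification needs.
#' Calibration is always user-supplied: it is never inferred from pixel
#' data and has no defaults, so omitting a required field is an error
#' rather than a silent assumption of 1.
#'
#' @param fps Frame rate in Hz (time-lapse videos).
#' @param pixel_size In-plane pixel size in micrometres per pixel
#'   (assumed isotropic in-plane).
#' @param z_step Axial step between slices in micrometres (z-stacks only).
#' @return An object of class `calibration`.
#' @examples
#' calibration(fps = 150, pixel_size = 0.65)
#' @export
calibration <- function(fps = NULL, pixel_size = NULL, z_step = NULL) {
  for (nm in c("fps", "pixel_size", "z_step")) {
    v <- get(nm)
    if (!is.null(v)) check_positive(v, nm)
  }
  structure(list(fps = fps, pixel_size = pixel_size, z_step = z_step),
            class = "calibration")
}

#' Calibrated time-lapse video container
#'
#' Stores a grayscale movie as a `time x height x width` integer array
#' together with its calibration. Axis order is fixed as
#' (time, row, column) with row 1 at the top of the image and x increasing
#' with column index; frame timestamps are `(frame - 1) / fps` seconds.
#'
#' @param frames 3D integer array `(T, H, W)` of non-negative intensities
#'   (8- or 16-bit range), or a single `H x W` matrix for a 1-frame video.
#' @param fps Frame rate in Hz.
#' @param pixel_size Micrometres per pixel.
#' @return An object of class `video_sequence` with elements `frames`,
#'   `fps`, `pixel_size` and `bits` (8 or 16, inferred from the range).
#' @seealso [read_video()], [write_video()]
#' @export
video_sequence <- function(frames, fps, pixel_size) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    zf_stop("format", "frames must be a (time, height, width) array")
  if (dim(frames)[1] < 1L) zf_stop("format", "video needs at least one frame")
  check_positive(fps, "fps")
  check_positive(pixel_size, "pixel_size")
  storage.mode(frames) <- "integer"
  if (anyNA(frames) || min(frames) < 0L)
    zf_stop("format", "intensities must be non-negative integers")
  bits <- if (max(frames) > 255L) 16L else 8L
  structure(list(frames = frames, fps = fps, pixel_size = pixel_size,
                 bits = bits),
            class = "video_sequence")
}

#' Calibrated 3D image stack container
#'
#' Stores a confocal-like z-stack as a `z x y x x` array with anisotropic
#' voxel calibration `(dz, dy, dx)` in micrometres.
#'
#' @param voxels 3D numeric/integer array `(Z, Y, X)`; may be binary for
#'   segmentation results.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   all strictly positive.
#' @return An object of class `voxel_stack`.
#' @seealso [read_stack()], [segment_vessels()]
#' @export
voxel_stack <- function(voxels, voxel_size) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    zf_stop("format", "voxels must be a (z, y, x) array")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    zf_stop("bad_argument", "voxel_size must be 3 positive numbers (dz, dy, dx)")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
            class = "voxel_stack")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Acquisition calibration\n")
  if (!is.null(x$fps)) cat(sprintf("  frame rate : %g Hz\n", x$fps))
  if (!is.null(x$pixel_size)) cat(sprintf("  pixel size : %g um/px\n", x$pixel_size))
  if (!is.null(x$z_step)) cat(sprintf("  z step     : %g um\n", x$z_step))
  invisible(x)
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Video sequence: %d frames of %d x %d px (%d-bit)\n", d[1], d[2], d[3], x$bits))
  cat(sprintf("  %g fps, %g um/px, duration %.3f s\n",
              x$fps, x$pixel_size, d[1] / x$fps))
  invisible(x)
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  vs <- x$voxel_size
  cat(sprintf("Voxel stack: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel %g x %g x %g um, z extent %.1f um\n",
              vs[1], vs[2], vs[3], d[1] * vs[1]))
  invisible(x)
}

#' @export
dim.video_sequence <- function(x) dim(x$frames)

#' @export
dim.voxel_stack <- function(x) dim(x$voxels)

# Number of frames / duration helpers used throughout.
n_frames <- function(video) dim(video$frames)[1]
frame_times <- function(video) (seq_len(n_frames(video)) - 1) / video$fps
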