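# Readers/writers for the standard formats the pipeline touches:
# multi-page grayscale TIFF for images, CSV + JSON sidecar for reports.

#' Read a multi-page grayscale TIFF as a calibrated video
#'
#' Pages are taken in file order as frames. Calibration is attached
#' unchanged from `calib`; it is required because pixel data carry no
#' trustworthy physical scale.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param calib A [calibration()] with `fps` and `pixel_size` set.
#' @return A [video_sequence()].
#' @seealso [write_video()]
#' @export
read_video <- function(path, calib) {
  frames <- read_tiff_pages(path)
  if (is.null(calib$fps) || is.null(calib$pixel_size))
    zf_stop("bad_argument", "calibration must supply fps and pixel_size")
  video_sequence(frames, fps = calib$fps, pixel_size = calib$pixel_size)
}

#' Read a multi-page grayscale TIFF as a calibrated z-stack
#'
#' The z dimension equals the page count; the voxel size is
#' `(z_step, pixel_size, pixel_size)` from the calibration.
#'
#' @param path Path to a multi-page grayscale TIFF ordered by z.
#' @param calib A [calibration()] with `pixel_size` and `z_step` set.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, calib) {
  voxels <- read_tiff_pages(path)
  if (is.null(calib$pixel_size) || is.null(calib$z_step))
    zf_stop("bad_argument", "calibration must supply pixel_size and z_step")
  voxel_stack(voxels, c(calib$z_step, calib$pixel_size, calib$pixel_size))
}

# Shared TIFF page reader: returns a (pages, H, W) integer array and
# rejects RGB or ragged pages.
read_tiff_pages <- function(path) {
  if (!file.exists(path)) zf_stop("missing_file", "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) zf_stop("format", "TIFF has no pages: %s", path)
  if (!all(vapply(pages, is.matrix, logical(1))))
    zf_stop("format", "non-grayscale (multi-channel) TIFF: %s", path)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    zf_stop("format", "ragged TIFF pages (differing sizes): %s", path)
  out <- array(0L, c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

#' Write a video or stack as a multi-page grayscale TIFF
#'
#' Pixel values round-trip bit-exactly through [read_video()] /
#' [read_stack()] (integers stored at 8 or 16 bits per sample).
#'
#' @param x A [video_sequence()] or [voxel_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_video <- function(x, path) {
  if (inherits(x, "video_sequence")) {
    arr <- x$frames; bits <- x$bits
  } else if (inherits(x, "voxel_stack")) {
    arr <- x$voxels
    storage.mode(arr) <- "integer"
    bits <- if (max(arr) > 255L) 16L else 8L
  } else zf_stop("bad_argument", "x must be a video_sequence or voxel_stack")
  maxv <- 2^bits - 1
  pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / maxv)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
  if (inherits(ok, "try-error")) zf_stop("io", "cannot write TIFF: %s", path)
  invisible(path)
}

#' @rdname write_video
#' @export
write_stack <- write_video

#' Write a measurement report to CSV with a JSON sidecar
#'
#' The CSV holds one row per measured entity with full numeric precision
#' (17 significant digits, so a write/read round trip reproduces every
#' value bit-exactly). A JSON sidecar `<path>.json` keeps the complete
#' per-beat / per-track / per-component detail that does not fit the flat
#' table.
#'
#' @param report A report object ([cardiac_report()], [flow_report()],
#'   [vessel_volume()], [compare_groups()], [screening_efficiency()]) or a
#'   list of reports of one kind; an empty list writes a header-only file.
#' @param path Output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  single <- inherits(report, c("cardiac_report", "velocity_report",
                               "vessel_volume_report", "group_comparison",
                               "efficiency_summary"))
  reports <- if (single) list(report) else report
  if (!is.list(reports)) zf_stop("bad_argument", "report must be a report object or list")
  rows <- lapply(reports, as.data.frame)
  df <- if (length(rows)) do.call(rbind, rows) else data.frame()
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) zf_stop("io", "cannot write: %s", path)
  on.exit(close(con), add = TRUE)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    writeLines(character(0), con)
  } else {
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    out[num] <- lapply(df[num], fmt_num)
    write.csv(out, con, row.names = FALSE, quote = FALSE)
  }
  sidecar <- lapply(reports, function(r) {
    r <- unclass(r)
    lapply(r, function(el) if (is.object(el) && !is.data.frame(el))
      unclass(el) else el)
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a report CSV written by [write_report()]
#'
#' @param path CSV path.
#' @return A data frame (zero rows for a header-only file).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) zf_stop("missing_file", "no such file: %s", path)
  if (file.size(path) <= 1) return(data.frame())
  read.csv(path, stringsAsFactors = FALSE)
}
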