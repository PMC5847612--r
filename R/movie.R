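#' Movie containers
#'
#' A *movie* is a calibrated 2D+time image stack. Two flavours are used
#' throughout the package:
#'
#' * `channel_movie()` — raw fluorescence intensities of a single channel
#'   (CFP, YPet or a nuclear marker); values are non-negative.
#' * `ratio_movie()` — a FRET/CFP ratio stack together with a logical
#'   validity mask (`TRUE` = the ratio is defined at that pixel).
#'
#' Arrays are indexed `[row, column, frame]`. Columns run along the
#' anterior–posterior axis: position (µm) increases posteriorly, so
#' border *regression* is a position increase. The physical position of
#' column `j` is `(j - 1) * pixel_size_um`; frame `k` is at time
#' `(k - 1) * frame_dt` minutes.
#'
#' @param data numeric 3D array `[row, col, frame]`.
#' @param frame_dt frame interval in minutes.
#' @param pixel_size_um pixel size in µm.
#' @param channel channel name (`"CFP"`, `"YPet"`, `"nuclei"`, ...).
#' @param mask logical array of the same shape as `data`; defaults to
#'   all-valid.
#' @return An object of class `channel_movie` or `ratio_movie`.
#' @name movies
NULL

#' @rdname movies
#' @export
channel_movie <- function(data, frame_dt, pixel_size_um, channel = "CFP") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(data < 0, na.rm = TRUE)) {
    stop("channel intensities must be non-negative")
  }
  check_calibration(frame_dt, pixel_size_um)
  structure(
    list(data = data, frame_dt = frame_dt, pixel_size_um = pixel_size_um,
         channel = channel),
    class = "channel_movie"
  )
}

#' @rdname movies
#' @export
ratio_movie <- function(data, frame_dt, pixel_size_um, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  check_calibration(frame_dt, pixel_size_um)
  if (is.null(mask)) {
    mask <- array(TRUE, dim(data))
  }
  stopifnot(is.logical(mask), identical(dim(mask), dim(data)))
  if (any(!is.finite(data[mask]))) {
    stop("ratio values must be finite wherever the mask is TRUE")
  }
  structure(
    list(data = data, mask = mask, frame_dt = frame_dt,
         pixel_size_um = pixel_size_um),
    class = "ratio_movie"
  )
}

check_calibration <- function(frame_dt, pixel_size_um) {
  stopifnot(is.numeric(frame_dt), length(frame_dt) == 1L, frame_dt > 0,
            is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  invisible(TRUE)
}

#' @export
print.channel_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<channel_movie '%s'> %d x %d px, %d frames, dt %g min, %g um/px\n",
              x$channel, d[1], d[2], d[3], x$frame_dt, x$pixel_size_um))
  invisible(x)
}

#' @export
print.ratio_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ratio_movie> %d x %d px, %d frames, dt %g min, %g um/px, %.1f%% valid\n",
              d[1], d[2], d[3], x$frame_dt, x$pixel_size_um,
              100 * mean(x$mask)))
  invisible(x)
}

n_frames <- function(movie) dim(movie$data)[3]

frame_times <- function(movie) (seq_len(n_frames(movie)) - 1) * movie$frame_dt

#' Write a movie as multi-frame 32-bit TIFF with a calibration sidecar
#'
#' TIFF samples are stored normalised to `[0, 1]`; the affine value range
#' together with the calibration (frame interval, pixel size, channel,
#' movie type) is written to a JSON sidecar at `<path>.json` so that
#' [load_movie()] can restore physical values. Storage quantises to
#' 32-bit levels, i.e. a reconstruction error of at most
#' `(hi - lo) * 2^-32`. For ratio movies, masked-out pixels are stored as
#' the reserved sample value 0 and valid samples occupy `[0.02, 0.98]`.
#'
#' @param movie a [channel_movie()] or [ratio_movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  is_ratio <- inherits(movie, "ratio_movie")
  stopifnot(is_ratio || inherits(movie, "channel_movie"))
  data <- movie$data
  vals <- if (is_ratio) data[movie$mask] else data
  if (length(vals) == 0L) stop("movie has no valid pixels to write")
  lo <- min(vals)
  hi <- max(vals)
  span <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(data)[3]), function(k) {
    fr <- data[, , k]
    s <- (fr - lo) / span
    if (is_ratio) {
      s <- 0.02 + 0.96 * s
      s[!movie$mask[, , k]] <- 0
    }
    pmin(pmax(s, 0), 1)
  })
  suppressWarnings(
    tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none")
  )
  meta <- list(
    type = if (is_ratio) "ratio" else "channel",
    frame_dt = movie$frame_dt,
    pixel_size_um = movie$pixel_size_um,
    value_lo = lo,
    value_hi = hi,
    channel = if (is_ratio) NULL else movie$channel
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF movie
#'
#' Reads 8/16-bit integer or 32-bit TIFF stacks. If a calibration sidecar
#' `<path>.json` (written by [write_movie()]) is present, physical values,
#' calibration and the validity mask are restored from it; otherwise raw
#' sample values are returned and `frame_dt` / `pixel_size_um` must be
#' supplied. Integer samples are promoted to double exactly; non-finite
#' values are masked.
#'
#' @param path TIFF path.
#' @param frame_dt,pixel_size_um calibration, required when no sidecar
#'   exists.
#' @param channel channel name for channel movies without a sidecar.
#' @return A [channel_movie()] or [ratio_movie()].
#' @export
load_movie <- function(path, frame_dt = NULL, pixel_size_um = NULL,
                       channel = "CFP") {
  sidecar <- paste0(path, ".json")
  has_sidecar <- file.exists(sidecar)
  # sidecar stacks are normalised: read as [0,1]; raw integer stacks are
  # read as.is so 8/16-bit values are preserved exactly
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !has_sidecar),
                     error = function(e) stop("not a readable TIFF: ", path))
  if (!is.list(frames)) frames <- list(frames)
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop("inconsistent frame shapes inside the TIFF stack")
  }
  d <- dim(frames[[1]])
  if (length(d) != 2L) stop("expected single-sample (grayscale) TIFF frames")
  data <- array(unlist(frames, use.names = FALSE), c(d[1], d[2], length(frames)))
  storage.mode(data) <- "double"

  if (has_sidecar) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    span <- meta$value_hi - meta$value_lo
    if (span <= 0) span <- 1
    if (identical(meta$type, "ratio")) {
      mask <- data > 0
      vals <- meta$value_lo + (data - 0.02) / 0.96 * span
      vals[!mask] <- NA_real_
      return(ratio_movie(vals, meta$frame_dt, meta$pixel_size_um, mask = mask))
    }
    vals <- meta$value_lo + data * span
    vals[vals < 0] <- 0
    return(channel_movie(vals, meta$frame_dt, meta$pixel_size_um,
                         channel = meta$channel %||% channel))
  }
  if (is.null(frame_dt) || is.null(pixel_size_um)) {
    stop("no calibration sidecar found; supply frame_dt and pixel_size_um")
  }
  if (any(!is.finite(data))) {
    mask <- is.finite(data)
    data[!mask] <- NA_real_
    return(ratio_movie(data, frame_dt, pixel_size_um, mask = mask))
  }
  channel_movie(data, frame_dt, pixel_size_um, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
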