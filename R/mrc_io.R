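# Minimal MRC2014 reader/writer for counted movies, plus a JSON sidecar for
# the metadata the MRC header cannot carry (frame period, super-resolution
# factor, electron value, gain flag). Supported modes: 0 (8-bit, stored
# unsigned), 1 (int16), 2 (float32), 6 (uint16). Data are stored x-fastest,
# matching the in-memory array layout (first index fastest).

MRC_HEADER_BYTES <- 1024L

#' Write an image stack as an MRC file
#'
#' @param data 2-D matrix or 3-D array of pixel values.
#' @param path Output path.
#' @param mode MRC mode: 0 (8-bit unsigned), 1 (int16), 2 (float32),
#'   6 (uint16), or `"auto"` to pick the smallest integer mode that holds
#'   the data (float32 for non-integer data).
#' @param pixel_size Pixel size in Angstrom written to the cell dimensions
#'   (`NA` writes 1).
#' @return The path, invisibly.
#' @export
write_mrc <- function(data, path, mode = "auto", pixel_size = NA_real_) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  vals <- as.vector(data)
  if (identical(mode, "auto")) {
    mode <- if (any(vals != round(vals))) 2L
    else if (min(vals) >= 0 && max(vals) <= 255) 0L
    else if (min(vals) >= 0 && max(vals) <= 65535) 6L
    else 2L
  }
  mode <- as.integer(mode)
  if (!mode %in% c(0L, 1L, 2L, 6L)) {
    stop_detchar(sprintf("unsupported MRC mode %d", mode), "mrc_mode")
  }
  apix <- if (is.finite(pixel_size)) pixel_size else 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d[1], d[2], d[3], mode, 0L, 0L, 0L, d[1], d[2], d[3])),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(d * apix, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(8), con)                                              # words 25-26
  writeBin(as.integer(c(0L, 20140L)), con, size = 4, endian = "little")  # exttyp, nversion
  writeBin(raw(96), con)  # words 29-52 (unused extra space)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(vals)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")  # nlabl
  writeBin(raw(800), con)
  write_mrc_data(vals, con, mode)
  invisible(path)
}

write_mrc_data <- function(vals, con, mode) {
  if (mode == 0L) {
    if (min(vals) < 0 || max(vals) > 255) {
      stop_detchar("values outside 0-255 cannot be stored in 8-bit mode", "mrc_range")
    }
    writeBin(as.raw(vals), con)
  } else if (mode == 1L) {
    if (min(vals) < -32768 || max(vals) > 32767) {
      stop_detchar("values outside int16 range", "mrc_range")
    }
    writeBin(as.integer(vals), con, size = 2, endian = "little")
  } else if (mode == 6L) {
    if (min(vals) < 0 || max(vals) > 65535) {
      stop_detchar("values outside uint16 range", "mrc_range")
    }
    v <- as.integer(vals)
    v[v > 32767L] <- v[v > 32767L] - 65536L  # two's complement for writeBin
    writeBin(v, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
}

#' Read an MRC file
#'
#' @param path Path to an MRC file (modes 0, 1, 2 or 6).
#' @return List with `data` (3-D array, integer-preserving for integer
#'   modes), `mode`, `pixel_size` (Angstrom, from the cell), and `dims`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop_detchar(sprintf("file not found: %s", path), "io")
  sz <- file.info(path)$size
  if (sz < MRC_HEADER_BYTES) {
    stop_detchar("truncated file: shorter than the 1024-byte MRC header (field: header)",
                 "mrc_header")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  floats <- readBin(con, "numeric", n = 6, size = 4, endian = "little")
  if (nx < 1 || ny < 1 || nz < 1 || nx > 1e6 || ny > 1e6 || nz > 1e6) {
    stop_detchar(sprintf("corrupt header: bad dimensions nx=%d ny=%d nz=%d (field: nx/ny/nz)",
                         nx, ny, nz), "mrc_header")
  }
  bytes_per <- c(`0` = 1L, `1` = 2L, `2` = 4L, `6` = 2L)[as.character(mode)]
  if (is.na(bytes_per)) {
    stop_detchar(sprintf("unknown MRC mode %d (field: mode)", mode), "mrc_mode")
  }
  npix <- as.numeric(nx) * ny * nz
  if (sz < MRC_HEADER_BYTES + npix * bytes_per) {
    stop_detchar("truncated file: data shorter than header promises (field: data)",
                 "mrc_truncated")
  }
  seek(con, MRC_HEADER_BYTES)
  data <- switch(as.character(mode),
    `0` = as.integer(readBin(con, "raw", n = npix)),
    `1` = readBin(con, "integer", n = npix, size = 2, signed = TRUE,
                  endian = "little"),
    `2` = readBin(con, "numeric", n = npix, size = 4, endian = "little"),
    `6` = readBin(con, "integer", n = npix, size = 2, signed = FALSE,
                  endian = "little")
  )
  dim(data) <- c(nx, ny, nz)
  apix <- if (ints[8] > 0) floats[1] / ints[8] else NA_real_
  list(data = data, mode = mode, pixel_size = apix, dims = c(nx, ny, nz))
}

#' Write a counted movie with its metadata sidecar
#'
#' Writes the frames as MRC (8-bit by default, as counted movies are
#' stored in practice; 16-bit unsigned when counts require it) and the
#' acquisition metadata as a JSON sidecar at `<path>.json`.
#'
#' @param movie A [superres_movie].
#' @param path Output MRC path.
#' @param mode MRC mode (see [write_mrc()]).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, mode = "auto") {
  stopifnot(inherits(movie, "superres_movie"))
  write_mrc(movie$data, path, mode = mode, pixel_size = movie$pixel_size)
  meta <- list(
    pixel_size = movie$pixel_size,
    frame_period = movie$frame_period,
    exposure_time = movie$exposure_time,
    n_frames = n_frames(movie),
    superres_factor = movie$superres_factor,
    electron_value = movie$electron_value,
    gain_corrected = FALSE
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a counted movie and its metadata
#'
#' Loads the MRC stack integer-preservingly and merges metadata from the
#' JSON sidecar `<path>.json` when present; missing metadata fall back to
#' explicit defaults with a warning.
#'
#' @param path MRC path.
#' @return List with `movie` (a [superres_movie]) and `metadata`.
#' @export
read_movie <- function(path) {
  mrc <- read_mrc(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warn_detchar("no metadata sidecar found; using defaults (frame period 1/60 s, super-res factor 2, electron value 16)",
                 "missing_metadata")
    list()
  }
  default <- function(name, value) if (!is.null(meta[[name]])) meta[[name]] else value
  frame_period <- default("frame_period", 1 / 60)
  n_fr <- mrc$dims[3]
  movie <- superres_movie(
    mrc$data,
    frame_period = frame_period,
    exposure_time = default("exposure_time", n_fr * frame_period),
    electron_value = default("electron_value", 16L),
    superres_factor = default("superres_factor", 2L),
    pixel_size = default("pixel_size", mrc$pixel_size)
  )
  list(movie = movie, metadata = meta)
}
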