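#' Super-resolution counted movie container
#'
#' A dose-fractionated counted movie as produced by an event-based counting
#' detector in super-resolution mode: an integer array of recorded counts
#' (each detected event contributes `electron_value` to one super-resolution
#' pixel), plus the pixel geometry and timing needed to turn counts into
#' dose rates.
#'
#' @param data Integer array `superres rows x superres cols x frames`.
#' @param frame_period Seconds per frame.
#' @param exposure_time Total effective exposure in seconds (for simulated
#'   movies, the whole number of counting windows actually simulated).
#' @param electron_value Counts per detected event.
#' @param superres_factor Super-resolution subdivision per physical-pixel
#'   axis (1 = physical sampling, 2 = 4 subpixels per physical pixel).
#' @param pixel_size Physical pixel size in Angstrom at the specimen, or
#'   `NA` when unknown.
#'
#' @return Object of class `superres_movie`.
#' @export
superres_movie <- function(data, frame_period, exposure_time,
                           electron_value = 16L, superres_factor = 2L,
                           pixel_size = NA_real_) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) {
    stop_detchar("`data` must be a 2-D image or 3-D frame stack", "bad_movie")
  }
  check_scalar(frame_period, "frame_period", positive = TRUE)
  check_scalar(exposure_time, "exposure_time", positive = TRUE)
  structure(
    list(
      data = data,
      frame_period = frame_period,
      exposure_time = exposure_time,
      electron_value = as.integer(electron_value),
      superres_factor = as.integer(superres_factor),
      pixel_size = pixel_size
    ),
    class = "superres_movie"
  )
}

#' @export
print.superres_movie <- function(x, ...) {
  d <- dim(x$data)
  cat("<superres_movie>\n")
  cat(sprintf("  %d x %d super-res pixels (%dx super-res), %d frame(s)\n",
              d[1], d[2], x$superres_factor, d[3]))
  cat(sprintf("  frame period %g s, exposure %g s, %d counts/event\n",
              x$frame_period, x$exposure_time, x$electron_value))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [superres_movie].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$data)[3]

#' Sum a movie over frames
#'
#' @param movie A [superres_movie].
#' @return Matrix of summed counts on the super-resolution grid.
#' @export
sum_frames <- function(movie) {
  d <- dim(movie$data)
  if (d[3] == 1L) return(movie$data[, , 1])
  rowSums(movie$data, dims = 2)
}

#' Bin a movie to physical pixels, in electron units
#'
#' Sums the movie over frames, merges each block of
#' `superres_factor^2` subpixels into its physical pixel, and divides by
#' `electron_value`, giving detected electrons per physical pixel.
#'
#' @param movie A [superres_movie].
#' @return Matrix of detected electrons per physical pixel.
#' @export
bin_to_physical <- function(movie) {
  img <- sum_frames(movie)
  k <- movie$superres_factor
  img <- bin_block(img, k)
  img / movie$electron_value
}

# Block-sum a matrix by factor k along both axes.
bin_block <- function(img, k) {
  if (k == 1L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (nr %% k != 0L || nc %% k != 0L) {
    img <- img[seq_len(nr - nr %% k), seq_len(nc - nc %% k), drop = FALSE]
    nr <- nrow(img); nc <- ncol(img)
  }
  img <- rowsum(img, rep(seq_len(nr / k), each = k))
  t(rowsum(t(img), rep(seq_len(nc / k), each = k)))
}
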