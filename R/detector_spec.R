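#' Detector specification for the counting-sensor simulator
#'
#' Bundles the physical parameters of an event-based counting detector.
#' The central parameter is the saturation constant `a` of the dose-response
#' relation `y = (1 - exp(-a x)) / a`, where `x` is the input dose rate and
#' `y` the detected (counted) dose rate, both in electrons per physical pixel
#' per second (eps). `1/a` is the maximum attainable detected rate.
#'
#' @param a Saturation constant in seconds * pixel / electron. The simulator
#'   realizes it as the length of the per-pixel internal counting window:
#'   every window records at most one event, so arrivals sharing a window are
#'   merged (coincidence loss).
#' @param false_positive_rate Dark-count events per physical pixel per second
#'   (spatially and temporally uniform Poisson).
#' @param psf_sigma Optional Gaussian blur of the illumination scene, in
#'   physical-pixel units; 0 disables blurring.
#' @param electron_value Counts recorded per detected event (16 for the
#'   detector characterized here).
#' @param subpixels_per_axis Super-resolution subdivision per physical pixel
#'   axis; 2 gives the usual 4 super-resolution pixels per physical pixel.
#' @param frame_period Seconds per output movie frame. Default 1/60 s
#'   (60 frames per second); 0.0166 s is an accepted alternative convention.
#' @param saturation_input_eps Input dose rate above which the simulator
#'   refuses to run: beyond this rate the real device saturates and produces
#'   artifacts rather than data.
#'
#' @return An object of class `detector_spec`.
#' @examples
#' spec <- detector_spec(a = 0.007)
#' spec$frame_period
#' @export
detector_spec <- function(a = 0.007,
                          false_positive_rate = 2.86e-6,
                          psf_sigma = 0,
                          electron_value = 16L,
                          subpixels_per_axis = 2L,
                          frame_period = 1 / 60,
                          saturation_input_eps = 80) {
  check_scalar(a, "a", positive = TRUE)
  check_scalar(false_positive_rate, "false_positive_rate", nonneg = TRUE)
  check_scalar(psf_sigma, "psf_sigma", nonneg = TRUE)
  check_scalar(frame_period, "frame_period", positive = TRUE)
  check_scalar(saturation_input_eps, "saturation_input_eps", positive = TRUE)
  electron_value <- as.integer(electron_value)
  subpixels_per_axis <- as.integer(subpixels_per_axis)
  if (electron_value < 1L) stop_detchar("`electron_value` must be >= 1", "bad_arg")
  if (subpixels_per_axis < 1L) stop_detchar("`subpixels_per_axis` must be >= 1", "bad_arg")
  structure(
    list(
      a = a,
      false_positive_rate = false_positive_rate,
      psf_sigma = psf_sigma,
      electron_value = electron_value,
      subpixels_per_axis = subpixels_per_axis,
      frame_period = frame_period,
      saturation_input_eps = saturation_input_eps
    ),
    class = "detector_spec"
  )
}

#' @export
print.detector_spec <- function(x, ...) {
  cat("<detector_spec>\n")
  cat(sprintf("  a                    : %g s*px/e- (saturation %.1f eps)\n", x$a, 1 / x$a))
  cat(sprintf("  false positive rate  : %g events/px/s\n", x$false_positive_rate))
  cat(sprintf("  psf sigma            : %g physical px\n", x$psf_sigma))
  cat(sprintf("  electron value       : %d counts/event\n", x$electron_value))
  cat(sprintf("  subpixels per axis   : %d\n", x$subpixels_per_axis))
  cat(sprintf("  frame period         : %g s\n", x$frame_period))
  cat(sprintf("  saturation input eps : %g\n", x$saturation_input_eps))
  invisible(x)
}

#' Illumination scenes
#'
#' A scene is the relative illumination pattern on the physical-pixel grid
#' together with the input dose rate at full intensity. `scene_uniform()`
#' builds a flood-beam scene; `scene_edge()` builds a slanted straight step
#' edge (one side at relative intensity 1, the other 0), optionally blurred
#' by a Gaussian system PSF and averaged over each pixel aperture.
#'
#' @param shape Integer vector `c(nrow, ncol)` of physical-pixel grid
#'   dimensions (a single number is recycled to a square).
#' @param base_input_eps Input dose rate `x` at relative intensity 1.0, in
#'   electrons per physical pixel per second.
#' @param intensity Relative intensity in `[0, 1]` for the uniform scene.
#'
#' @return An object of class `scene`: list with `shape`, `intensity_map`
#'   (matrix in `[0,1]`) and `base_input_eps`.
#' @examples
#' sc <- scene_uniform(c(64, 64), base_input_eps = 15)
#' range(sc$intensity_map)
#' @export
scene_uniform <- function(shape, base_input_eps, intensity = 1) {
  shape <- normalize_shape(shape)
  check_scalar(base_input_eps, "base_input_eps", nonneg = TRUE)
  check_scalar(intensity, "intensity", nonneg = TRUE)
  if (intensity > 1) stop_detchar("`intensity` must be in [0, 1]", "bad_arg")
  new_scene(matrix(intensity, shape[1], shape[2]), base_input_eps)
}

#' @rdname scene_uniform
#' @param edge_angle Edge angle in degrees from the image row axis (the edge
#'   is nominally vertical; positive angles tilt it clockwise).
#' @param edge_offset Edge intercept offset from the scene center, in
#'   physical pixels along the column axis.
#' @param psf_sigma Gaussian blur applied to the step before pixel-aperture
#'   averaging, in physical pixels.
#' @param oversample Sub-samples per pixel axis used for the pixel-aperture
#'   average of the (blurred) step.
#' @export
scene_edge <- function(shape, base_input_eps, edge_angle, edge_offset = 0,
                       psf_sigma = 0, oversample = 16L) {
  shape <- normalize_shape(shape)
  check_scalar(base_input_eps, "base_input_eps", nonneg = TRUE)
  check_scalar(edge_angle, "edge_angle")
  check_scalar(edge_offset, "edge_offset")
  check_scalar(psf_sigma, "psf_sigma", nonneg = TRUE)
  nr <- shape[1]; nc <- shape[2]
  s <- as.integer(oversample)
  # Sub-sample coordinates of pixel interiors (pixel i spans [i-0.5, i+0.5]).
  sub <- (seq_len(s) - 0.5) / s - 0.5
  rows <- rep(seq_len(nr), each = s) + rep(sub, times = nr)
  cols <- rep(seq_len(nc), each = s) + rep(sub, times = nc)
  theta <- edge_angle * pi / 180
  r0 <- (nr + 1) / 2
  c0 <- (nc + 1) / 2 + edge_offset
  # Signed distance from the edge line col = c0 + tan(theta) * (row - r0),
  # measured along the edge normal; bright side is distance > 0.
  edge_col <- c0 + tan(theta) * (rows - r0)
  dmat <- (outer(rep(1, nr * s), cols) - outer(edge_col, rep(1, nc * s))) * cos(theta)
  if (psf_sigma > 0) {
    # Evaluate the Gaussian-blurred step only near the edge; the profile is
    # exactly 0/1 beyond ~8 sigma.
    prof <- (dmat > 0) + 0
    band <- abs(dmat) < 8 * psf_sigma
    prof[band] <- stats::pnorm(dmat[band] / psf_sigma)
  } else {
    prof <- (dmat > 0) + 0.5 * (dmat == 0)
  }
  # Average the s x s sub-samples of each pixel (pixel-aperture integration).
  g <- rep(seq_len(nr), each = s)
  prof <- rowsum(prof, g) / s
  prof <- t(rowsum(t(prof), rep(seq_len(nc), each = s)) / s)
  new_scene(prof, base_input_eps)
}

new_scene <- function(intensity_map, base_input_eps) {
  if (any(intensity_map < 0 | intensity_map > 1)) {
    stop_detchar("intensity_map values must lie in [0, 1]", "bad_scene")
  }
  structure(
    list(
      shape = dim(intensity_map),
      intensity_map = intensity_map,
      base_input_eps = base_input_eps
    ),
    class = "scene"
  )
}

normalize_shape <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- c(shape, shape)
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop_detchar("`shape` must be one or two positive integers", "bad_arg")
  }
  shape
}
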