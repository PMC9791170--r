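#' Detected dose rate of a counted movie
#'
#' Converts recorded super-resolution counts to the detected dose rate in
#' electrons per physical pixel per second (eps): the mean super-resolution
#' pixel intensity per second, divided by the value of a single detected
#' electron (`electron_value`, 16 here) and multiplied by the number of
#' super-resolution pixels per physical pixel (4 here).
#'
#' @param movie A [superres_movie].
#' @return Detected dose rate in eps.
#' @examples
#' spec <- detector_spec(a = 0.007, false_positive_rate = 0)
#' sim <- simulate_flat_movie(spec, scene_uniform(64, 16), 0.5, seed = 2)
#' intensity_to_detected_eps(sim$movie)
#' @export
intensity_to_detected_eps <- function(movie) {
  stopifnot(inherits(movie, "superres_movie"))
  if (movie$exposure_time <= 0) stop_detchar("zero exposure time", "bad_arg")
  mean_intensity <- sum(as.numeric(movie$data)) / prod(dim(movie$data)[1:2])
  (mean_intensity / movie$exposure_time) / movie$electron_value *
    movie$superres_factor^2
}

#' Build an input-dose ladder from a magnification series
#'
#' Under constant illumination, the electron flux per detector pixel scales
#' with the specimen area each pixel sees, i.e. with the square of the
#' calibrated pixel size. The point with the smallest pixel flux (highest
#' magnification, smallest pixel size) is taken as the zero-coincidence-loss
#' anchor: its input rate is set equal to its detected rate, and the input
#' rate at every other magnification is scaled by the pixel-area ratio,
#' `input_m = input_ref * (p_ref / p_m)^(-2)` with `p` in Angstrom per
#' physical pixel (equivalently `input_ref * (p_m / p_ref)^2`).
#'
#' @param series `data.frame` with columns `magnification`, `pixel_size`
#'   (Angstrom per physical pixel) and `mean_detected_eps`.
#' @param correct_anchor The anchor assumption biases every input rate low
#'   by the anchor's own (small) coincidence loss. With
#'   `correct_anchor = TRUE` the ladder is built, a dose-response model
#'   fitted, the anchor's input recovered by inverting that model at its
#'   detected rate, and the ladder rebuilt once from the corrected anchor.
#'   Off by default, which reproduces the standard procedure.
#' @return `data.frame` of dose pairs with columns `input_eps` and
#'   `detected_eps`, ordered as the input series.
#' @examples
#' ser <- data.frame(magnification = c(120000, 60000),
#'                   pixel_size = c(0.5, 1.0),
#'                   mean_detected_eps = c(10, 35))
#' build_dose_ladder(ser)
#' @export
build_dose_ladder <- function(series, correct_anchor = FALSE) {
  req <- c("magnification", "pixel_size", "mean_detected_eps")
  if (!all(req %in% names(series))) {
    stop_detchar("series needs columns magnification, pixel_size, mean_detected_eps",
                 "bad_arg")
  }
  if (anyDuplicated(series$magnification)) {
    stop_detchar("duplicate magnifications in series", "bad_arg")
  }
  if (any(series$pixel_size <= 0)) stop_detchar("pixel sizes must be > 0", "bad_arg")
  if (nrow(series) > 1) {
    ps_by_mag <- series$pixel_size[order(series$magnification)]
    if (any(diff(ps_by_mag) > 0)) {
      warn_detchar("pixel size does not decrease with magnification", "nonmonotonic")
    }
  }
  ref <- which.min(series$pixel_size)  # highest magnification = lowest pixel flux
  input_ref <- series$mean_detected_eps[ref]
  input <- input_ref * (series$pixel_size / series$pixel_size[ref])^2
  pairs <- data.frame(input_eps = input, detected_eps = series$mean_detected_eps)
  if (isTRUE(correct_anchor) && nrow(pairs) >= 2) {
    model <- fit_dose_response(pairs)
    input_ref2 <- invert_detected(model, series$mean_detected_eps[ref])
    pairs$input_eps <- input_ref2 * (series$pixel_size / series$pixel_size[ref])^2
  }
  pairs
}

#' Fit the coincidence-loss dose-response model
#'
#' Least-squares fit of the saturation constant `a` in the dose response
#' `y = (1 - exp(-a x)) / a`, where `x` is the input and `y` the detected
#' dose rate (both eps). The objective is the sum of squared deviations in
#' detected-rate space, minimized by deterministic bounded 1-D search over
#' `a` in `[1e-6, 1]`.
#'
#' @param pairs `data.frame` with columns `input_eps` and `detected_eps`
#'   (at least two pairs with distinct inputs).
#' @return Object of class `dose_response_model` with fields `a`,
#'   `residual_rms` (eps) and `n_points`.
#' @examples
#' m <- fit_dose_response(data.frame(input_eps = c(16, 34, 78),
#'                                   detected_eps = c(15, 30, 60)))
#' m$a
#' coincidence_loss(m, 15)
#' @export
fit_dose_response <- function(pairs) {
  if (!all(c("input_eps", "detected_eps") %in% names(pairs))) {
    stop_detchar("pairs needs columns input_eps and detected_eps", "bad_arg")
  }
  x <- pairs$input_eps; y <- pairs$detected_eps
  if (length(unique(x)) < 2) stop_detchar("need >= 2 pairs with distinct inputs", "bad_arg")
  if (any(x <= 0) || any(y <= 0)) stop_detchar("dose rates must be > 0", "bad_arg")
  if (any(y > x + sqrt(.Machine$double.eps))) {
    stop_detchar("detected rate exceeds input rate; ladder inconsistent", "bad_arg")
  }
  obj <- function(a) sum((y - (1 - exp(-a * x)) / a)^2)
  opt <- stats::optimize(obj, interval = c(1e-6, 1), tol = 1e-12)
  a <- opt$minimum
  if (a < 1e-5) {
    warn_detchar("no measurable coincidence loss; `a` at lower search bound",
                 "no_loss")
  }
  structure(
    list(a = a,
         residual_rms = sqrt(opt$objective / length(x)),
         n_points = length(x)),
    class = "dose_response_model"
  )
}

#' @export
print.dose_response_model <- function(x, ...) {
  cat("<dose_response_model>\n")
  cat(sprintf("  a = %.6g s*px/e-  (saturation limit %.1f eps)\n", x$a, 1 / x$a))
  cat(sprintf("  residual rms %.3g eps over %d points\n", x$residual_rms, x$n_points))
  invisible(x)
}

as_model <- function(model) {
  if (inherits(model, "dose_response_model")) return(model)
  if (is.numeric(model) && length(model) == 1 && model > 0) {
    return(structure(list(a = model, residual_rms = NA_real_, n_points = 0L),
                     class = "dose_response_model"))
  }
  stop_detchar("`model` must be a dose_response_model or a positive `a`", "bad_arg")
}

#' Dose-response predictions, inversion and coincidence loss
#'
#' `predict_detected()` evaluates `y = (1 - exp(-a x)) / a`;
#' `invert_detected()` applies the closed-form inverse
#' `x = -log(1 - a y) / a`; `coincidence_loss()` returns the lost fraction
#' `1 - y(x)/x` (0 at `x = 0` by continuity); `saturation_limit()` returns
#' `1/a`, the supremum of detectable dose rates.
#'
#' @param model A `dose_response_model` (or a bare numeric `a`).
#' @param x Input dose rate(s), eps (`>= 0`).
#' @param y Detected dose rate(s), eps; must be below `1/a`.
#' @return Dose rates in eps, or a loss fraction in `[0, 1)`.
#' @examples
#' m <- fit_dose_response(data.frame(input_eps = c(16, 34, 78),
#'                                   detected_eps = c(15, 30, 60)))
#' predict_detected(m, 78)
#' invert_detected(m, 12)
#' round(100 * coincidence_loss(m, c(15, 30, 66)))
#' @export
predict_detected <- function(model, x) {
  m <- as_model(model)
  if (any(x < 0)) stop_detchar("input dose rate must be >= 0", "bad_arg")
  (1 - exp(-m$a * x)) / m$a
}

#' @rdname predict_detected
#' @export
invert_detected <- function(model, y) {
  m <- as_model(model)
  if (any(y < 0)) stop_detchar("detected dose rate must be >= 0", "bad_arg")
  if (any(y >= 1 / m$a)) {
    stop_detchar(sprintf("detected rate at or above saturation (1/a = %.1f eps); not invertible",
                         1 / m$a), "above_saturation")
  }
  -log(1 - m$a * y) / m$a
}

#' @rdname predict_detected
#' @export
coincidence_loss <- function(model, x) {
  m <- as_model(model)
  if (any(x < 0)) stop_detchar("input dose rate must be >= 0", "bad_arg")
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- 1 - predict_detected(m, x[nz]) / x[nz]
  out
}

#' @rdname predict_detected
#' @export
saturation_limit <- function(model) 1 / as_model(model)$a

#' Plan an exposure for a target specimen dose
#'
#' Computes the exposure time delivering `target_dose` electrons per square
#' Angstrom at the given detected dose rate and pixel size, the number of
#' whole movie frames at the camera frame rate, and the dose actually
#' achieved by the rounded frame count.
#'
#' @param target_dose Target total dose, e-/A^2.
#' @param pixel_size Physical pixel size, Angstrom.
#' @param detected_eps Detected dose rate, eps.
#' @param frame_rate Movie frame rate, frames per second.
#' @return List with `exposure_time` (s), `n_frames`, `achieved_dose`
#'   (e-/A^2 recomputed from the rounded frame count).
#' @examples
#' plan_exposure(60, 0.599, 15, 60)$n_frames
#' @export
plan_exposure <- function(target_dose, pixel_size, detected_eps, frame_rate) {
  check_scalar(target_dose, "target_dose", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(detected_eps, "detected_eps", positive = TRUE)
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  exposure <- target_dose * pixel_size^2 / detected_eps
  nf <- as.integer(round(exposure * frame_rate))
  achieved <- nf / frame_rate * detected_eps / pixel_size^2
  list(exposure_time = exposure, n_frames = nf, achieved_dose = achieved)
}

#' @rdname plan_exposure
#' @param exposure_time Exposure time in seconds.
#' @return `frames_for_exposure()`: the whole number of movie frames
#'   covering the exposure at the camera frame rate.
#' @examples
#' frames_for_exposure(c(1.264, 0.666, 0.333), 60)
#' @export
frames_for_exposure <- function(exposure_time, frame_rate) {
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  as.integer(round(exposure_time * frame_rate))
}

#' Dose rate on the specimen
#'
#' @param detected_eps Detected dose rate, eps.
#' @param pixel_size Physical pixel size, Angstrom.
#' @return Specimen dose rate, e-/A^2/s (`detected_eps / pixel_size^2`).
#' @examples
#' specimen_dose_rate(12, 0.6)
#' @export
specimen_dose_rate <- function(detected_eps, pixel_size) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  detected_eps / pixel_size^2
}

#' False positives as a percentage of the dose rate
#'
#' @param rate Dark-count rate, events per physical pixel per second.
#' @param dose_rate_eps Dose rate the false positives are compared to, eps.
#' @return Percentage `100 * rate / dose_rate_eps`.
#' @examples
#' false_positive_percent(2.86e-6, 0.1)
#' @export
false_positive_percent <- function(rate, dose_rate_eps) {
  check_scalar(rate, "rate", nonneg = TRUE)
  check_scalar(dose_rate_eps, "dose_rate_eps", positive = TRUE)
  100 * rate / dose_rate_eps
}
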