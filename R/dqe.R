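#' DQE(0) by the noise-binning method
#'
#' The movie is summed over frames and converted to detected electrons per
#' physical pixel. For each bin factor `b` the image is block-binned and the
#' normalized noise `v(b) = Var[block sums] / (b^2 * mean)` computed; for
#' Poisson statistics `v(b) = 1` at every `b`, and spatial correlations
#' (or sub-Poisson counting) move the large-`b` plateau `v_inf` away from 1.
#' The plateau is the mean of the largest adjacent pair of bin factors whose
#' values agree within `plateau_tol` (relative); if no pair agrees the
#' illumination is not statistically uniform and an error of class
#' `detchar_no_plateau` is raised.
#'
#' With the incident exposure known, the absolute
#' `DQE(0) = (mean / N_in) / v_inf` where `N_in` is incident electrons per
#' physical pixel (`incident_eps * exposure time`). Without it, the
#' Poisson-relative figure `1 / v_inf` is returned and flagged as such
#' (`mode = "poisson_relative"`) rather than silently assuming full
#' detection.
#'
#' @param flood A statistically uniform flood [superres_movie], or a plain
#'   matrix of detected electrons per physical pixel.
#' @param incident_eps Optional incident (input) dose rate in eps; may be
#'   obtained by inverting a fitted dose-response model.
#' @param exposure_time Exposure in seconds; taken from the movie when
#'   `flood` is a movie.
#' @param bin_factors Block-binning factors (powers of two up to 64).
#' @param plateau_tol Relative tolerance defining the plateau.
#' @return Object of class `dqe0_estimate`: `dqe0`, `mode` (`"absolute"` or
#'   `"poisson_relative"`), `v` (per-factor table), `v_inf`, `mean_electrons`.
#' @examples
#' img <- matrix(rpois(512 * 512, 20), 512, 512)
#' dqe0_noise_binning(img)$dqe0
#' @export
dqe0_noise_binning <- function(flood, incident_eps = NULL, exposure_time = NULL,
                               bin_factors = 2^(0:6), plateau_tol = 0.05) {
  if (inherits(flood, "superres_movie")) {
    if (is.null(exposure_time)) exposure_time <- flood$exposure_time
    img <- bin_to_physical(flood)
  } else if (is.matrix(flood)) {
    img <- flood
  } else {
    stop_detchar("`flood` must be a superres_movie or a matrix", "bad_arg")
  }
  bin_factors <- sort(unique(as.integer(bin_factors)))
  bmax <- max(bin_factors)
  nr <- nrow(img) - nrow(img) %% bmax
  nc <- ncol(img) - ncol(img) %% bmax
  if (nr < 2 * bmax || nc < 2 * bmax) {
    stop_detchar("image too small for the requested bin factors", "bad_arg")
  }
  img <- img[seq_len(nr), seq_len(nc)]
  mean0 <- mean(img)
  if (mean0 <= 0) stop_detchar("flood image has zero mean", "bad_arg")
  v <- vapply(bin_factors, function(b) {
    blk <- bin_block(img, b)
    stats::var(as.vector(blk)) / (b^2 * mean0)
  }, numeric(1))
  if (any(v <= 0)) stop_detchar("non-positive variance estimate", "bad_arg")
  v_inf <- NA_real_
  for (i in rev(seq_len(length(bin_factors) - 1))) {
    if (abs(v[i + 1] - v[i]) / v[i] < plateau_tol) {
      v_inf <- mean(v[c(i, i + 1)])
      break
    }
  }
  if (!is.finite(v_inf)) {
    stop_detchar("noise-binning plateau not reached; illumination not uniform?",
                 "no_plateau")
  }
  if (!is.null(incident_eps)) {
    if (is.null(exposure_time)) {
      stop_detchar("`exposure_time` needed to use `incident_eps`", "bad_arg")
    }
    n_in <- incident_eps * exposure_time
    dqe0 <- (mean0 / n_in) / v_inf
    mode <- "absolute"
  } else {
    dqe0 <- 1 / v_inf
    mode <- "poisson_relative"
  }
  structure(
    list(dqe0 = dqe0, mode = mode,
         v = data.frame(bin_factor = bin_factors, v = v),
         v_inf = v_inf, mean_electrons = mean0),
    class = "dqe0_estimate"
  )
}

#' @export
print.dqe0_estimate <- function(x, ...) {
  cat(sprintf("<dqe0_estimate> DQE(0) = %.3f (%s), v_inf = %.3f\n",
              x$dqe0, x$mode, x$v_inf))
  invisible(x)
}

#' Compose the DQE curve
#'
#' `DQE(s) = DQE(0) * MTF(s)^2 / NNPS(s)` pointwise on the MTF's frequency
#' axis. By convention for counting data with negligible coincidence loss,
#' the NNPS defaults to unity at all spatial frequencies.
#'
#' @param dqe0 Scalar DQE(0), or a `dqe0_estimate`.
#' @param mtf A `transfer_curves` object from [edge_to_mtf()].
#' @param nnps Optional normalized [radial_spectrum]; interpolated onto the
#'   MTF frequency axis. `NULL` means unity.
#' @return The `transfer_curves` object with `dqe0`, `dqe` and
#'   `nnps_assumed` filled in.
#' @examples
#' tc <- structure(list(freq = c(0, 0.5, 1), mtf = c(1, 0.84, 0.5)),
#'                 class = "transfer_curves")
#' round(dqe_curve(0.937, tc)$dqe, 2)
#' @export
dqe_curve <- function(dqe0, mtf, nnps = NULL) {
  if (inherits(dqe0, "dqe0_estimate")) dqe0 <- dqe0$dqe0
  check_scalar(dqe0, "dqe0", nonneg = TRUE)
  stopifnot(inherits(mtf, "transfer_curves"))
  if (is.null(nnps)) {
    nn <- rep(1, length(mtf$freq))
    mtf$nnps_assumed <- "unity"
  } else {
    stopifnot(inherits(nnps, "radial_spectrum"))
    if (is.null(nnps$norm_band)) {
      stop_detchar("nnps must be normalized (see normalize_nps)", "bad_arg")
    }
    if (max(nnps$freq) < max(mtf$freq)) {
      stop_detchar("nnps does not cover the MTF frequency axis", "bad_arg")
    }
    nn <- stats::approx(nnps$freq, nnps$power, xout = mtf$freq, rule = 2)$y
    mtf$nnps_assumed <- "measured"
  }
  mtf$dqe0 <- dqe0
  mtf$dqe <- dqe0 * mtf$mtf^2 / nn
  mtf
}

#' Theoretical DQE of an ideal square-pixel detector
#'
#' The aperture-limited maximum `|sinc|^2`: 1 at zero frequency and
#' `(2/pi)^2 = 0.405` at physical Nyquist.
#'
#' @param freq Frequencies in physical-Nyquist units.
#' @return DQE values.
#' @examples
#' theoretical_square_pixel_dqe(c(0, 0.5, 1))
#' @export
theoretical_square_pixel_dqe <- function(freq) {
  nu <- freq / 2  # cycles per physical pixel
  ifelse(nu == 0, 1, (sin(pi * nu) / (pi * nu))^2)
}
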