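#' Rotationally averaged power spectrum
#'
#' Computes the raw 2-D discrete Fourier power `|F|^2` (unnormalized forward
#' transform, so that the total power including DC equals `N` times the
#' image sum of squares) and averages it over equal-width annular frequency
#' bins. The frequency axis is expressed in units of the *physical* Nyquist
#' frequency (0.5 cycles per physical pixel): super-resolution input extends
#' to 2.0, physical-pixel input to 1.0. The DC term is excluded from the
#' annuli; annulus membership is by half-open bin of the radial frequency
#' magnitude.
#'
#' @param image Numeric matrix (a super-resolution or physical-pixel image),
#'   or a [superres_movie] (summed over frames). A centered square crop is
#'   taken if the image is rectangular.
#' @param n_bins Number of radial bins (default 256).
#' @param superres_factor Samples per physical pixel along one axis. Taken
#'   from the movie when `image` is a [superres_movie]; defaults to 2
#'   otherwise.
#' @return Object of class `radial_spectrum`: `data.frame`-like list with
#'   `freq` (bin centers, physical-Nyquist units), `power` (mean raw power
#'   per annulus), `n` (Fourier samples per annulus), plus `n_bins`,
#'   `norm_band` (`NULL` until [normalize_nps()]), and `total_power`
#'   metadata.
#' @examples
#' img <- matrix(rpois(256 * 256, 10), 256, 256)
#' sp <- radial_power_spectrum(img, n_bins = 64)
#' head(sp$freq)
#' @export
radial_power_spectrum <- function(image, n_bins = 256L,
                                  superres_factor = NULL) {
  if (inherits(image, "superres_movie")) {
    if (is.null(superres_factor)) superres_factor <- image$superres_factor
    image <- sum_frames(image)
  }
  if (is.null(superres_factor)) superres_factor <- 2L
  if (!is.matrix(image)) stop_detchar("`image` must be a matrix", "bad_arg")
  if (any(!is.finite(image))) stop_detchar("non-finite pixels in image", "bad_arg")
  if (min(dim(image)) < 64) stop_detchar("image too small (need >= 64 x 64)", "bad_arg")
  n <- min(dim(image))
  if (!all(dim(image) == n)) {
    r0 <- floor((nrow(image) - n) / 2)
    c0 <- floor((ncol(image) - n) / 2)
    image <- image[r0 + seq_len(n), c0 + seq_len(n)]
  }
  P <- Mod(stats::fft(image))^2
  total_power <- sum(P)
  # fftfreq in cycles per sample; physical Nyquist = 0.5 / superres_factor
  # cycles per sample, so divide by that to get physical-Nyquist units.
  fr <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1))) / n
  f_unit <- 0.5 / superres_factor
  r <- sqrt(outer(fr^2, fr^2, `+`)) / f_unit
  fmax <- superres_factor  # radial coverage kept to the full axis range
  width <- fmax / n_bins
  bin <- floor(r / width) + 1L
  keep <- r > 0 & bin <= n_bins
  groups <- as.vector(bin[keep])
  sums <- rep(0, n_bins); cnts <- rep(0L, n_bins); ksum <- rep(0, n_bins)
  agg_s <- rowsum(as.vector(P[keep]), groups)
  ids <- as.integer(rownames(agg_s))
  sums[ids] <- agg_s
  cnts[ids] <- as.vector(rowsum(rep(1L, length(groups)), groups))
  # Per-sample subpixel-placement kernel K(fx, fy): uniform placement of
  # each event among the subpixels multiplies the correlated (within-pixel
  # pair) part of the spectrum by K, needed to interpret NNPS suppression.
  if (superres_factor > 1L) {
    # nu in cycles per physical pixel = cycles/sample * samples per pixel
    phi <- placement_kernel(abs(fr) * superres_factor, superres_factor)
    K <- outer(phi^2, phi^2)
    ksum[ids] <- as.vector(rowsum(as.vector(K[keep]), groups))
  } else {
    ksum[ids] <- cnts[ids]
  }
  nonzero <- cnts > 0
  structure(
    list(freq = (which(nonzero) - 0.5) * width,
         power = sums[nonzero] / cnts[nonzero],
         n = cnts[nonzero],
         placement_weight = ksum[nonzero] / cnts[nonzero],
         n_bins = as.integer(n_bins),
         norm_band = NULL,
         superres_factor = superres_factor,
         total_power = total_power),
    class = "radial_spectrum"
  )
}

#' @export
print.radial_spectrum <- function(x, ...) {
  cat("<radial_spectrum>\n")
  cat(sprintf("  %d bins over [0, %.2f] physical Nyquist\n",
              length(x$freq), max(x$freq)))
  if (!is.null(x$norm_band)) {
    cat(sprintf("  normalized over [%.2f, %.2f]\n", x$norm_band[1], x$norm_band[2]))
  }
  invisible(x)
}

#' Normalize a noise power spectrum
#'
#' Divides the radial power by its mean over the normalization band,
#' by convention the average between 1.5x and 2.0x physical Nyquist for
#' super-resolution data (where counting shot noise is essentially white).
#' Idempotent up to the band mean; scale invariant.
#'
#' @param spectrum A [radial_power_spectrum()] result.
#' @param band Length-2 frequency interval (physical-Nyquist units) whose
#'   bin-center mean defines the normalization. Data that do not cover the
#'   default band (e.g. physical-pixel-only input) raise a
#'   `detchar_band_unavailable` error; pass an explicit `band` instead.
#' @return The spectrum with `power` scaled and `norm_band` recorded.
#' @export
normalize_nps <- function(spectrum, band = c(1.5, 2.0)) {
  stopifnot(inherits(spectrum, "radial_spectrum"))
  denom <- band_mean(spectrum, band)
  if (denom <= 0) stop_detchar("normalization band mean is zero", "bad_arg")
  spectrum$power <- spectrum$power / denom
  spectrum$norm_band <- band
  spectrum
}

band_mean <- function(spectrum, band, what = "power") {
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel)) {
    stop_detchar(sprintf("band [%g, %g] not covered by spectrum (max freq %.2f)",
                         band[1], band[2], max(spectrum$freq)),
                 "band_unavailable")
  }
  # Weight by Fourier samples per annulus: the band mean then equals the
  # mean power over all Fourier samples in the band.
  sum(spectrum[[what]][sel] * spectrum$n[sel]) / sum(spectrum$n[sel])
}

# Per-axis characteristic function of uniform placement among k equally
# spaced subpixels (offsets ((1:k)-(k+1)/2)/k physical px): Dirichlet
# kernel sin(pi nu) / (k sin(pi nu / k)), nu in cycles per physical pixel.
placement_kernel <- function(nu, k) {
  out <- rep(1, length(nu))
  nz <- abs(nu) > 1e-12
  out[nz] <- sin(pi * nu[nz]) / (k * sin(pi * nu[nz] / k))
  out
}

#' Coincidence loss from NPS suppression
#'
#' Coincidence loss suppresses the low-frequency noise power of a flood
#' exposure. This estimator takes the mean of the normalized NPS over the
#' low-frequency band (0.06 to 0.08 physical Nyquist, the approximate
#' location of the minimum) and converts the deficit `S = 1 - mean(NNPS)`
#' to a loss estimate.
#'
#' With `method = "suppression"` (default) the deficit itself is returned,
#' clipped to `[0, 1]`. With `method = "dead_time"` the deficit is mapped
#' through the dead-time counting relation: for a counter with per-pixel
#' windows of length `a`, the flood NPS is
#' `mean + (var - mean) * K(f)` with variance-to-mean ratio `R = exp(-a x)`
#' and `K(f)` the subpixel-placement kernel stored in the spectrum, so the
#' normalized band mean `B` gives `R - 1 = (B - 1) / (K_low - B * K_norm)`
#' and the coincidence loss `1 - (1 - R)/(-log R)` follows without knowing
#' `a` or `x`. The raw deficit approaches twice the loss at low rates; the
#' dead-time mapping is the estimate comparable to the dose-response model.
#'
#' @param nnps A normalized spectrum from [normalize_nps()].
#' @param band Low-frequency band, physical-Nyquist units.
#' @param method `"suppression"` or `"dead_time"` (see Details).
#' @return Estimated coincidence-loss fraction in `[0, 1]`.
#' @export
nps_coincidence_loss <- function(nnps, band = c(0.06, 0.08),
                                 method = c("suppression", "dead_time")) {
  stopifnot(inherits(nnps, "radial_spectrum"))
  method <- match.arg(method)
  if (is.null(nnps$norm_band)) {
    stop_detchar("spectrum must be normalized first (see normalize_nps)", "bad_arg")
  }
  b <- band_mean(nnps, band)
  if (method == "suppression") return(min(max(1 - b, 0), 1))
  k_low <- band_mean(nnps, band, "placement_weight")
  k_norm <- band_mean(nnps, nnps$norm_band, "placement_weight")
  denom <- k_low - b * k_norm
  if (denom <= 0) return(0)
  r <- 1 + (b - 1) / denom
  if (r >= 1) return(0)
  if (r <= 0) return(1)
  min(max(1 - (1 - r) / (-log(r)), 0), 1)
}

#' Estimate the false-positive (dark-count) rate
#'
#' From a beam-off movie: total recorded counts divided by the electron
#' value, the number of *physical* pixels, and the total exposure time.
#'
#' @param beam_off_movie A [superres_movie] acquired with the beam blanked.
#' @return Events per physical pixel per second.
#' @export
false_positive_rate_estimate <- function(beam_off_movie) {
  stopifnot(inherits(beam_off_movie, "superres_movie"))
  if (beam_off_movie$exposure_time <= 0) stop_detchar("zero exposure time", "bad_arg")
  d <- dim(beam_off_movie$data)
  n_phys <- prod(d[1:2]) / beam_off_movie$superres_factor^2
  sum(as.numeric(beam_off_movie$data)) / beam_off_movie$electron_value /
    n_phys / beam_off_movie$exposure_time
}
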