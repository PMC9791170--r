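#' Locate a slanted straight edge
#'
#' Finds the subpixel edge position in every row (or column, whichever axis
#' the edge is closer to perpendicular to) as the centroid of the intensity
#' gradient, then fits a straight line through the per-row locations by
#' least squares.
#'
#' @param image Numeric matrix containing a single straight step edge.
#' @param roi Optional `c(row_min, row_max, col_min, col_max)` rectangle;
#'   default is the whole image.
#' @param pitch Pixel pitch of `image` in physical-pixel units (1 for a
#'   physical-pixel image, 0.5 for super-resolution).
#' @param angle_range Acceptable `abs(angle)` interval in degrees; outside
#'   it the slanted-edge method is unreliable and an error of class
#'   `detchar_edge_angle` is raised.
#' @return Object of class `edge_fit`: `angle` (degrees), `intercept`
#'   (column of the edge at the first ROI row), `per_row` locations,
#'   `rms_line_residual` (pixels of `image`), `roi`, `transposed`, `pitch`.
#' @examples
#' img <- outer(1:64, 1:64, function(r, c) (c > 32 + 0.1 * r) + 0)
#' fit_edge(img)$angle
#' @export
fit_edge <- function(image, roi = NULL, pitch = 1, angle_range = c(1, 15)) {
  if (!is.matrix(image)) stop_detchar("`image` must be a matrix", "bad_arg")
  if (!is.null(roi)) {
    image <- image[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  } else {
    roi <- c(1L, nrow(image), 1L, ncol(image))
  }
  # Orient so the edge runs down the rows (per-row crossing of columns):
  # compare mean absolute gradient across columns vs across rows.
  gc_ <- mean(abs(diff(colMeans(image))))
  gr_ <- mean(abs(diff(rowMeans(image))))
  transposed <- gr_ > gc_
  if (transposed) image <- t(image)
  nr <- nrow(image); nc <- ncol(image)
  locs <- rep(NA_real_, nr)
  for (r in seq_len(nr)) {
    g <- diff(image[r, ])
    ag <- abs(g)
    if (max(ag) <= 0) next
    pk <- which.max(stats::filter(ag, rep(1 / 5, 5), sides = 2))
    w <- max(1L, pk - 10L):min(length(g), pk + 10L)
    num <- sum((w + 0.5) * g[w]); den <- sum(g[w])
    if (abs(den) < .Machine$double.eps) next
    locs[r] <- num / den
  }
  ok <- is.finite(locs)
  if (sum(ok) < max(8L, nr / 4)) {
    stop_detchar("no edge found: gradient too weak in most rows", "no_edge")
  }
  fit <- stats::lm.fit(cbind(1, which(ok)), locs[ok])
  slope <- fit$coefficients[2]
  resid_rms <- sqrt(mean(fit$residuals^2))
  angle <- atan(slope) * 180 / pi
  if (abs(angle) < angle_range[1] || abs(angle) > angle_range[2]) {
    stop_detchar(sprintf(
      "edge too steep/shallow for the slanted-edge method (angle %.2f deg, need %g-%g)",
      abs(angle), angle_range[1], angle_range[2]), "edge_angle")
  }
  if (resid_rms > 2) {
    warn_detchar(sprintf("edge not straight (rms line residual %.2f px)", resid_rms),
                 "edge_crooked")
  }
  structure(
    list(angle = unname(angle),
         intercept = unname(fit$coefficients[1] + slope),
         slope = unname(slope),
         rows = which(ok),
         per_row = locs[ok],
         rms_line_residual = resid_rms,
         roi = roi,
         transposed = transposed,
         pitch = pitch),
    class = "edge_fit"
  )
}

#' Slanted-edge MTF estimation
#'
#' Standard slanted-edge procedure: every pixel of the region is projected
#' onto the edge-normal coordinate; the edge-spread function (ESF) is the
#' binned mean profile at `1/oversample` physical-pixel pitch; the
#' line-spread function (LSF) is its central finite difference, apodized
#' with a Hann window spanning the full projection; the MTF is the DFT
#' magnitude of the LSF normalized to 1 at zero frequency. The
#' finite-difference and bin-aperture transfer factors are divided out.
#' Frequencies are reported in physical-Nyquist units (1.0 = 0.5 cycles per
#' physical pixel).
#'
#' @param image Numeric matrix with a straight slanted edge.
#' @param edge An [fit_edge()] result for the same image (computed if
#'   missing).
#' @param oversample ESF bins per physical pixel (default 8).
#' @param roi Optional ROI passed to [fit_edge()] when `edge` is missing.
#' @param pitch Pixel pitch of `image` in physical-pixel units.
#' @param f_max Maximum frequency reported, physical-Nyquist units.
#' @param esf_halfwidth Half-width of the ESF analysis window around the
#'   edge, physical px. Distances beyond it carry no edge signal, only
#'   noise, so a tight window improves the estimate; widen it for PSFs with
#'   long tails.
#' @return Object of class `transfer_curves` with `freq`, `mtf`, and the
#'   `edge` fit; `dqe`/`dqe0` slots are filled by [dqe_curve()].
#' @examples
#' img <- outer(1:96, 1:96, function(r, c) pnorm(c - 48 - 0.09 * r, sd = 0.7))
#' tc <- edge_to_mtf(img)
#' tc$mtf[which.min(abs(tc$freq - 1))]
#' @export
edge_to_mtf <- function(image, edge = NULL, oversample = 8L, roi = NULL,
                        pitch = 1, f_max = 2, esf_halfwidth = 16) {
  if (is.null(edge)) edge <- fit_edge(image, roi = roi, pitch = pitch)
  pitch <- edge$pitch
  r <- edge$roi
  image <- image[r[1]:r[2], r[3]:r[4], drop = FALSE]
  if (edge$transposed) image <- t(image)
  nr <- nrow(image); nc <- ncol(image)
  theta <- edge$angle * pi / 180
  # Signed distance (in image pixels) from each pixel center to the edge
  # line col = intercept + slope * row, measured along the edge normal.
  rows <- seq_len(nr); cols <- seq_len(nc)
  edge_col <- edge$intercept + edge$slope * (rows - 1)
  d <- (matrix(cols, nr, nc, byrow = TRUE) - edge_col) * cos(theta)
  d <- d * pitch  # physical-pixel units
  delta <- 1 / oversample
  # Trim to a symmetric range so both tails of the ESF are fully populated.
  halfrange <- min(max(d), -min(d), esf_halfwidth) - delta
  keep <- abs(d) <= halfrange
  db <- floor(d[keep] / delta)
  vals <- image[keep]
  agg <- rowsum(vals, db)
  cnt <- as.vector(rowsum(rep(1, length(db)), db))
  ids <- as.integer(rownames(agg))
  full <- seq(min(ids), max(ids))
  esf <- rep(NA_real_, length(full))
  esf[match(ids, full)] <- agg / cnt
  # Linear interpolation over any empty bins.
  if (anyNA(esf)) {
    esf <- stats::approx(full[!is.na(esf)], esf[!is.na(esf)], xout = full,
                         rule = 2)$y
  }
  if (length(esf) < 4 * oversample) {
    stop_detchar("insufficient samples per ESF bin (region too narrow)", "esf_bins")
  }
  n <- length(esf)
  lsf <- (esf[c(2:n, n)] - esf[c(1, 1:(n - 1))]) / (2 * delta)
  # Hann window centered on the LSF peak, spanning the full projection.
  peak <- which.max(abs(stats::filter(abs(lsf), rep(1 / 3, 3), sides = 2,
                                      circular = TRUE)))
  idx <- seq_len(n)
  half <- max(peak - 1, n - peak)
  wnd <- 0.5 * (1 + cos(pi * (idx - peak) / half))
  wnd[abs(idx - peak) > half] <- 0
  lsf <- lsf * wnd
  ft <- stats::fft(lsf)
  freq_cpp <- (seq_len(n) - 1) / (n * delta)   # cycles per physical pixel
  f <- 2 * freq_cpp                            # physical-Nyquist units
  sel <- f <= f_max
  mtf <- Mod(ft)[sel]
  fsel <- f[sel]
  # Correct the central-difference derivative and ESF bin-aperture responses.
  nu <- fsel / 2
  dcorr <- ifelse(nu == 0, 1, abs(sin(2 * pi * nu * delta) / (2 * pi * nu * delta)))
  bcorr <- ifelse(nu == 0, 1, abs(sin(pi * nu * delta) / (pi * nu * delta)))
  mtf <- mtf / (dcorr * bcorr)
  mtf <- mtf / mtf[1]
  structure(
    list(freq = fsel, mtf = mtf, dqe0 = NULL, dqe = NULL,
         nnps_assumed = NULL, edge = edge, oversample = as.integer(oversample)),
    class = "transfer_curves"
  )
}

#' @export
print.transfer_curves <- function(x, ...) {
  cat("<transfer_curves>\n")
  at <- function(f) {
    i <- which.min(abs(x$freq - f)); x$mtf[i]
  }
  cat(sprintf("  MTF: %.3f at 0.5x Nyquist, %.3f at Nyquist (%d samples to %.2f)\n",
              at(0.5), at(1), length(x$freq), max(x$freq)))
  if (!is.null(x$dqe0)) {
    cat(sprintf("  DQE(0) = %.3f; DQE %.3f at 0.5x Nyquist, %.3f at Nyquist\n",
                x$dqe0, x$dqe[which.min(abs(x$freq - 0.5))],
                x$dqe[which.min(abs(x$freq - 1))]))
  }
  invisible(x)
}

#' Interpolate a transfer curve at given frequencies
#'
#' @param curves A `transfer_curves` object.
#' @param freq Frequencies in physical-Nyquist units.
#' @param what `"mtf"` or `"dqe"`.
#' @return Interpolated values.
#' @export
curve_at <- function(curves, freq, what = c("mtf", "dqe")) {
  what <- match.arg(what)
  y <- curves[[what]]
  if (is.null(y)) stop_detchar(sprintf("curve has no %s component", what), "bad_arg")
  stats::approx(curves$freq, y, xout = freq, rule = 2)$y
}
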