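#' Simulate a counted flood-beam movie
#'
#' Event-based counting-sensor simulator. Per physical pixel, time is
#' partitioned into internal counting windows of length `a` (the saturation
#' constant). The number of electrons arriving in a window is Poisson with
#' mean `a * x` (`x` = local input dose rate in eps); a window records
#' exactly one detected event when at least one electron arrives, so extra
#' arrivals in the same window are merged (coincidence loss). The expected
#' detected rate is therefore exactly `(1 - exp(-a x)) / a`. Each detected
#' event is placed at a uniformly chosen subpixel of its physical pixel with
#' value `electron_value`; false positives arrive as an independent uniform
#' Poisson process. Windows are assigned to output movie frames by their
#' start time.
#'
#' The requested `duration` is rounded to a whole number of counting
#' windows; the effective exposure (`n_windows * a`) is stored in the movie
#' and used by all rate estimators, so the closed-form dose response holds
#' exactly in expectation.
#'
#' Implementation note: detected counts per pixel and frame are drawn as
#' Binomial(windows in frame, `1 - exp(-a x)`) and subpixel placement as an
#' exact multinomial split, which is distributionally identical to looping
#' over every window but far faster; the merged-electron ground truth is
#' drawn from the zero-truncated Poisson conditional of occupied windows.
#'
#' @param spec A [detector_spec()].
#' @param scene A [scene_uniform()] or [scene_edge()] scene.
#' @param duration Requested exposure in seconds (at least one frame).
#' @param seed Integer seed; the same seed reproduces the movie and ground
#'   truth bit for bit.
#' @param ground_truth If `TRUE` (default), also return per-pixel emitted,
#'   detected, merged and false-positive counts. Electron conservation
#'   `detected + merged = emitted` holds per pixel on every run.
#'
#' @return List with elements `movie` (a [superres_movie]) and
#'   `ground_truth` (class `ground_truth`, or `NULL` when not requested).
#' @examples
#' spec <- detector_spec(a = 0.007, false_positive_rate = 0)
#' sim <- simulate_flat_movie(spec, scene_uniform(32, 15), duration = 0.2, seed = 1)
#' intensity_to_detected_eps(sim$movie)
#' @export
simulate_flat_movie <- function(spec, scene, duration, seed, ground_truth = TRUE) {
  stopifnot(inherits(spec, "detector_spec"), inherits(scene, "scene"))
  check_scalar(duration, "duration", positive = TRUE)
  if (duration < spec$frame_period) {
    stop_detchar("`duration` must cover at least one frame period", "bad_arg")
  }
  x_max <- scene$base_input_eps * max(scene$intensity_map)
  if (x_max > spec$saturation_input_eps) {
    stop_detchar(sprintf(
      "input dose rate %.1f eps exceeds the saturation limit (%g eps); the detector produces artifacts, not data, in this regime",
      x_max, spec$saturation_input_eps), "saturated")
  }

  a <- spec$a
  n_win <- max(1L, as.integer(round(duration / a)))
  exposure <- n_win * a
  # Window w starts at (w-1)*a; assign to frames by start time.
  frame_of <- pmin(floor((seq_len(n_win) - 1) * a / spec$frame_period),
                   ceiling(exposure / spec$frame_period) - 1) + 1L
  nf <- max(frame_of)
  m <- tabulate(frame_of, nbins = nf)

  nr <- scene$shape[1]; nc <- scene$shape[2]
  npix <- nr * nc
  lambda <- as.vector(a * scene$base_input_eps * scene$intensity_map)
  p <- -expm1(-lambda)
  k <- spec$subpixels_per_axis
  fp_rate <- spec$false_positive_rate

  with_seed(seed, {
    frames <- array(0L, dim = c(nr * k, nc * k, nf))
    detected <- integer(npix)
    fp_total <- integer(npix)
    for (f in seq_len(nf)) {
      D <- rbinom(npix, m[f], p)
      FP <- if (fp_rate > 0) rpois(npix, fp_rate * m[f] * a) else integer(npix)
      detected <- detected + D
      fp_total <- fp_total + FP
      frames[, , f] <- place_subpixels(D + FP, nr, nc, k) * spec$electron_value
    }
    gt <- NULL
    if (isTRUE(ground_truth)) {
      merged <- integer(npix)
      if (sum(detected) > 0) {
        idx <- rep.int(seq_len(npix), detected)
        lam <- lambda[idx]
        # Occupied windows hold zero-truncated Poisson(lambda) electrons.
        u <- exp(-lam) + runif(length(idx)) * (-expm1(-lam))
        extras <- qpois(u, lam) - 1L
        agg <- rowsum(extras, idx)
        merged[as.integer(rownames(agg))] <- agg
      }
      gt <- structure(list(
        emitted = matrix(detected + merged, nr, nc),
        detected = matrix(detected, nr, nc),
        merged = matrix(merged, nr, nc),
        false_positives = matrix(fp_total, nr, nc),
        seed = as.integer(seed)
      ), class = "ground_truth")
    }
    movie <- superres_movie(frames,
                            frame_period = spec$frame_period,
                            exposure_time = exposure,
                            electron_value = spec$electron_value,
                            superres_factor = k)
    list(movie = movie, ground_truth = gt)
  })
}

# Distribute per-pixel event counts uniformly among the k^2 subpixels of
# each physical pixel (exact multinomial via sequential binomial splits) and
# assemble the super-resolution frame.
place_subpixels <- function(counts, nr, nc, k) {
  nsub <- k * k
  if (nsub == 1L) return(matrix(counts, nr, nc))
  sr <- matrix(0L, nr * k, nc * k)
  remaining <- counts
  for (j in seq_len(nsub)) {
    cj <- if (j < nsub) rbinom(length(remaining), remaining, 1 / (nsub - j + 1)) else remaining
    remaining <- remaining - cj
    dr <- (j - 1L) %% k
    dc <- (j - 1L) %/% k
    sr[seq(1L + dr, by = k, length.out = nr),
       seq(1L + dc, by = k, length.out = nc)] <- matrix(cj, nr, nc)
  }
  sr
}

#' Simulate a slanted-edge acquisition
#'
#' Builds a straight step-edge scene (bright side at `base_input_eps`, dark
#' side 0), blurred by the detector's Gaussian PSF (`spec$psf_sigma`) and
#' averaged over each pixel aperture, then counts it as in
#' [simulate_flat_movie()]. The true system MTF (Gaussian times square pixel
#' aperture) is recorded in the returned movie's `edge_truth` field for
#' recovery tests.
#'
#' @inheritParams simulate_flat_movie
#' @param edge_angle Edge angle in degrees from the image row axis; the
#'   slanted-edge method needs `1 <= |angle| <= 15` degrees.
#' @param edge_offset Edge intercept offset from scene center, physical px.
#' @param base_input_eps Input dose rate on the bright side, eps.
#' @param shape Physical-pixel grid dimensions.
#' @return A [superres_movie] with an `edge_truth` list (`angle`, `offset`,
#'   `psf_sigma`, and `mtf(freq)` on the physical-Nyquist frequency axis).
#' @export
simulate_edge_movie <- function(spec, edge_angle, edge_offset = 0,
                                base_input_eps, duration, seed,
                                shape = c(256L, 256L)) {
  stopifnot(inherits(spec, "detector_spec"))
  if (abs(edge_angle) < 1 || abs(edge_angle) > 15) {
    stop_detchar("edge too steep/shallow for the slanted-edge method (need 1-15 degrees)",
                 "edge_angle")
  }
  sc <- scene_edge(shape, base_input_eps, edge_angle, edge_offset,
                   psf_sigma = spec$psf_sigma)
  sim <- simulate_flat_movie(spec, sc, duration, seed, ground_truth = FALSE)
  movie <- sim$movie
  sigma <- spec$psf_sigma
  movie$edge_truth <- list(
    angle = edge_angle,
    offset = edge_offset,
    psf_sigma = sigma,
    # freq in physical-Nyquist units; nu = freq/2 cycles per physical pixel
    mtf = function(freq) {
      nu <- freq / 2
      ap <- ifelse(nu == 0, 1, abs(sin(pi * nu) / (pi * nu)))
      exp(-2 * pi^2 * sigma^2 * nu^2) * ap
    }
  )
  movie
}

#' Simulate a beam-off (dark) acquisition
#'
#' Only false-positive events occur: a uniform Poisson process at
#' `spec$false_positive_rate` events per physical pixel per second, each
#' placed at a random subpixel with value `electron_value`.
#'
#' @inheritParams simulate_flat_movie
#' @param shape Physical-pixel grid dimensions.
#' @return A [superres_movie].
#' @export
simulate_beam_off <- function(spec, shape, duration, seed) {
  stopifnot(inherits(spec, "detector_spec"))
  check_scalar(duration, "duration", positive = TRUE)
  shape <- normalize_shape(shape)
  nr <- shape[1]; nc <- shape[2]
  npix <- nr * nc
  k <- spec$subpixels_per_axis
  nf <- max(1L, as.integer(ceiling(duration / spec$frame_period - 1e-9)))
  fdur <- rep(spec$frame_period, nf)
  fdur[nf] <- duration - (nf - 1) * spec$frame_period
  with_seed(seed, {
    frames <- array(0L, dim = c(nr * k, nc * k, nf))
    for (f in seq_len(nf)) {
      FP <- rpois(npix, spec$false_positive_rate * fdur[f])
      frames[, , f] <- place_subpixels(FP, nr, nc, k) * spec$electron_value
    }
    superres_movie(frames,
                   frame_period = spec$frame_period,
                   exposure_time = duration,
                   electron_value = spec$electron_value,
                   superres_factor = k)
  })
}

#' Simulate a ResLog table
#'
#' Generates `(particle count, resolution)` pairs from a straight line in
#' transformed-resolution versus `log10(N)` space, with optional Gaussian
#' noise on the transformed values, then inverse-transforms to Angstrom.
#'
#' @param slope,intercept Line parameters in transformed units per decade.
#' @param particle_counts Vector of particle counts (all `>= 1`).
#' @param noise_sd Gaussian noise SD on the transformed resolution.
#' @param transform Resolution transform: `"reciprocal"` (default,
#'   Angstrom^-1), `"identity"`, or `"reciprocal_squared"`.
#' @param seed Integer seed.
#' @return `data.frame` with columns `n_particles` and `resolution` (Angstrom).
#' @examples
#' tab <- simulate_reslog_table(0.063, 0.27, c(1e4, 1e5, 1e6), 0, seed = 1)
#' fit_reslog(tab)$slope
#' @export
simulate_reslog_table <- function(slope, intercept, particle_counts,
                                  noise_sd = 0, transform = "reciprocal",
                                  seed = 1L) {
  check_scalar(slope, "slope")
  check_scalar(intercept, "intercept")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(particle_counts < 1)) stop_detchar("particle counts must be >= 1", "bad_arg")
  tr <- get_reslog_transform(transform)
  with_seed(seed, {
    t_vals <- intercept + slope * log10(particle_counts) +
      rnorm(length(particle_counts), 0, noise_sd)
    if (any(!is.finite(tr$inverse(t_vals))) || any(tr$inverse(t_vals) <= 0)) {
      stop_detchar("transform not invertible on generated values (non-positive resolution)",
                   "bad_transform")
    }
    data.frame(n_particles = particle_counts, resolution = tr$inverse(t_vals))
  })
}
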