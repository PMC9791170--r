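# Independent oracles used across the suite.

# Brute-force event-by-event counting simulator: enumerates the Poisson
# electron count of every internal window of every pixel and merges
# arrivals sharing a window. Slow but transparent; used to validate the
# vectorized simulator.
brute_force_flood <- function(a, x, npix, duration, seed) {
  set.seed(seed)
  n_win <- max(1L, round(duration / a))
  emitted <- detected <- integer(npix)
  for (i in seq_len(npix)) {
    k <- rpois(n_win, a * x)
    emitted[i] <- sum(k)
    detected[i] <- sum(k > 0)
  }
  list(emitted = emitted, detected = detected,
       rate = sum(detected) / (npix * n_win * a),
       rate_se = sd(detected) / sqrt(npix) / (n_win * a))
}

# Analytic system MTF of the simulator's edge scenes: Gaussian PSF times
# square pixel aperture, frequency in physical-Nyquist units.
analytic_edge_mtf <- function(freq, sigma) {
  nu <- freq / 2
  ap <- ifelse(nu == 0, 1, abs(sin(pi * nu) / (pi * nu)))
  exp(-2 * pi^2 * sigma^2 * nu^2) * ap
}

# Detected-rate statistics straight from a simulation's ground truth.
gt_rate <- function(sim) {
  det <- as.vector(sim$ground_truth$detected)
  exposure <- sim$movie$exposure_time
  list(rate = mean(det) / exposure,
       se = sd(det) / sqrt(length(det)) / exposure)
}

# Tile-averaged normalized NPS of simulated flood exposures.
flood_nnps <- function(spec, x, shape, n_tiles, seed, n_bins = 256L,
                       duration = 1) {
  acc <- NULL
  for (t in seq_len(n_tiles)) {
    sim <- simulate_flat_movie(spec, scene_uniform(shape, x), duration,
                               seed = seed + t, ground_truth = FALSE)
    sp <- radial_power_spectrum(sim$movie, n_bins = n_bins)
    if (is.null(acc)) acc <- sp else acc$power <- acc$power + sp$power
  }
  acc$power <- acc$power / n_tiles
  normalize_nps(acc)
}

# The three-point measured dose ladder used throughout: detected rates of
# 15, 30 and 60 eps at input rates 16, 34 and 78 eps.
measured_pairs <- function() {
  read.csv(system.file("extdata", "dose_pairs.csv", package = "detchar"))
}
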