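test_that("edge fitting recovers a noiseless slanted edge to 0.05 degrees", {
  sc <- scene_edge(c(128, 96), 1, edge_angle = 5, psf_sigma = 0.4)
  e <- fit_edge(sc$intensity_map * 1000)
  expect_equal(e$angle, 5, tolerance = 0.05 / 5)
  expect_lt(e$rms_line_residual, 0.05)
})

test_that("vertical and flat edges are rejected as degenerate", {
  step <- cbind(matrix(0, 64, 32), matrix(1, 64, 32))
  expect_error(fit_edge(step), class = "detchar_edge_angle")
  expect_error(fit_edge(matrix(1, 64, 64)), class = "detchar_no_edge")
})

test_that("counted edge movies yield the edge angle within 0.2 degrees", {
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, psf_sigma = 0.5,
                        frame_period = 10)
  mov <- simulate_edge_movie(spec, 5, 0, 12, 87, seed = 13, shape = c(512, 128))
  e <- fit_edge(bin_to_physical(mov))
  expect_equal(e$angle, 5, tolerance = 0.2 / 5)
})

test_that("a horizontal edge is analysed through the transpose path", {
  sc <- scene_edge(c(128, 96), 1, edge_angle = 5, psf_sigma = 0.4)
  e <- fit_edge(t(sc$intensity_map))
  expect_true(e$transposed)
  expect_equal(abs(e$angle), 5, tolerance = 0.05)
})

test_that("an aperture-only edge gives the sinc MTF, 2/pi at physical Nyquist", {
  sc <- scene_edge(c(256, 96), 1, edge_angle = 5, psf_sigma = 0)
  tc <- edge_to_mtf(sc$intensity_map * 500, oversample = 8)
  expect_equal(tc$mtf[1], 1)
  expect_equal(curve_at(tc, 1), 2 / pi, tolerance = 0.02)
  sel <- tc$freq <= 1
  expect_lt(max(abs(tc$mtf[sel] - analytic_edge_mtf(tc$freq[sel], 0))), 0.02)
})

test_that("a Gaussian-blurred edge gives the Gaussian-times-aperture MTF", {
  sc <- scene_edge(c(256, 96), 1, edge_angle = 5, psf_sigma = 0.5)
  tc <- edge_to_mtf(sc$intensity_map * 500)
  sel <- tc$freq <= 1
  expect_lt(max(abs(tc$mtf[sel] - analytic_edge_mtf(tc$freq[sel], 0.5))), 0.02)
})

test_that("MTF recovery from counted edge data stays within 0.03 of truth", {
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, psf_sigma = 0.5,
                        frame_period = 10)
  # ~1040 electrons per physical pixel accumulated, as characterized
  mov <- simulate_edge_movie(spec, 5, 0, 12, 87, seed = 14, shape = c(512, 128))
  tc <- edge_to_mtf(bin_to_physical(mov))
  sel <- tc$freq <= 1
  expect_lt(max(abs(tc$mtf[sel] - mov$edge_truth$mtf(tc$freq[sel]))), 0.03)
})

test_that("MTF estimation is invariant to edge polarity", {
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, psf_sigma = 0.5,
                        frame_period = 10)
  mov <- simulate_edge_movie(spec, 5, 0, 12, 87, seed = 15, shape = c(256, 96))
  img <- bin_to_physical(mov)
  flipped <- img[, rev(seq_len(ncol(img)))]
  tc1 <- edge_to_mtf(img)
  tc2 <- edge_to_mtf(flipped)
  ref <- seq(0.1, 1, by = 0.1)
  expect_equal(curve_at(tc1, ref), curve_at(tc2, ref), tolerance = 0.03)
})

test_that("noise-binning DQE(0) is 1 for ideal Poisson counting", {
  set.seed(22)
  img <- matrix(rpois(2048 * 2048, 20), 2048, 2048)
  est <- dqe0_noise_binning(img)
  expect_equal(est$mode, "poisson_relative")
  expect_equal(est$dqe0, 1, tolerance = 0.05)
  expect_equal(est$v$v, rep(1, nrow(est$v)), tolerance = 0.1)
})

test_that("binomially thinned Poisson counting gives DQE(0) equal to the keep rate", {
  set.seed(23)
  emitted <- matrix(rpois(2048 * 2048, 25), 2048, 2048)
  kept <- matrix(rbinom(length(emitted), emitted, 0.8), 2048, 2048)
  est <- dqe0_noise_binning(kept, incident_eps = 25, exposure_time = 1)
  expect_equal(est$mode, "absolute")
  expect_equal(est$dqe0, 0.8, tolerance = 0.05)
})

test_that("noise-binning DQE(0) matches the direct SNR ratio on simulated floods", {
  a <- 0.007; x <- 12.5
  spec <- detector_spec(a = a, false_positive_rate = 0, frame_period = 2)
  sim <- simulate_flat_movie(spec, scene_uniform(1024, x), 2, seed = 24,
                             ground_truth = FALSE)
  est <- dqe0_noise_binning(sim$movie, incident_eps = x)
  det <- bin_to_physical(sim$movie)
  n_in <- x * sim$movie$exposure_time
  brute <- (mean(det)^2 / var(as.vector(det))) / n_in
  expect_equal(est$dqe0, brute, tolerance = 0.06)
  # window-counting is sub-Poisson: both routes land on (e^(ax)-1)/(ax)
  expect_equal(brute, (exp(a * x) - 1) / (a * x), tolerance = 0.03)
})

test_that("non-uniform illumination fails the plateau test", {
  set.seed(25)
  grad <- outer(seq(5, 50, length.out = 512), rep(1, 512))
  img <- matrix(rpois(512 * 512, as.vector(grad)), 512, 512)
  expect_error(dqe0_noise_binning(img), class = "detchar_no_plateau")
})

test_that("the DQE curve composes DQE(0) with the squared MTF", {
  tc <- structure(list(freq = c(0, 0.5, 1), mtf = c(1, 0.84, 0.5)),
                  class = "transfer_curves")
  out <- dqe_curve(0.937, tc)
  expect_equal(out$nnps_assumed, "unity")
  expect_equal(round(out$dqe, 2), c(0.94, 0.66, 0.23))
  # exactly multiplicative in dqe0
  out2 <- dqe_curve(2 * 0.937, tc)
  expect_equal(out2$dqe, 2 * out$dqe)
  # unity everywhere when everything is ideal
  ideal <- dqe_curve(1, structure(list(freq = c(0, 1), mtf = c(1, 1)),
                                  class = "transfer_curves"))
  expect_equal(ideal$dqe, c(1, 1))
})

test_that("a measured NNPS reshapes the DQE curve pointwise", {
  img <- matrix(rnorm(256 * 256), 256, 256)
  nn <- normalize_nps(radial_power_spectrum(img, n_bins = 64))
  nn$power <- rep(0.5, length(nn$power))
  tc <- structure(list(freq = c(0.25, 0.75), mtf = c(0.9, 0.6)),
                  class = "transfer_curves")
  out <- dqe_curve(0.9, tc, nnps = nn)
  expect_equal(out$dqe, 0.9 * c(0.9, 0.6)^2 / 0.5)
})

test_that("the square-pixel theoretical DQE has the textbook endpoints", {
  expect_equal(theoretical_square_pixel_dqe(0), 1)
  expect_equal(theoretical_square_pixel_dqe(1), (2 / pi)^2)
  expect_equal(round(theoretical_square_pixel_dqe(1), 1), 0.4)
  expect_equal(theoretical_square_pixel_dqe(0.5),
               (sin(pi / 4) / (pi / 4))^2)
})
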