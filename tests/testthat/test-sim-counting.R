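spec0 <- detector_spec(a = 0.007, false_positive_rate = 0, frame_period = 1)

test_that("empty beam with no dark counts gives an identically zero movie", {
  sim <- simulate_flat_movie(spec0, scene_uniform(32, 0), 1, seed = 1)
  expect_true(all(sim$movie$data == 0))
  expect_true(all(sim$ground_truth$emitted == 0))
})

test_that("electron conservation holds per pixel on every run", {
  for (seed in c(3, 17, 91)) {
    sc <- scene_edge(c(48, 48), 40, edge_angle = 6, psf_sigma = 0.7)
    sim <- simulate_flat_movie(detector_spec(a = 0.01, false_positive_rate = 1e-3,
                                             frame_period = 0.25),
                               sc, 1, seed = seed)
    gt <- sim$ground_truth
    expect_identical(gt$emitted, gt$detected + gt$merged)
    expect_true(all(gt$emitted >= 0) && all(gt$merged >= 0))
    # recorded counts = (detected + false positives) * electron_value
    expect_equal(sum(sim$movie$data) / 16, sum(gt$detected + gt$false_positives))
  }
})

test_that("simulated detected rates match the closed-form dose response", {
  a <- 0.007
  for (x in c(5, 15, 30, 60, 78)) {
    sim <- simulate_flat_movie(spec0, scene_uniform(256, x), 1,
                               seed = 100 + x)
    st <- gt_rate(sim)
    expected <- (1 - exp(-a * x)) / a
    expect_lt(abs(st$rate - expected), 3 * st$se)
    # and the movie-intensity route agrees with the ground-truth route
    expect_equal(intensity_to_detected_eps(sim$movie), st$rate, tolerance = 1e-12)
  }
})

test_that("vectorized simulator agrees with the brute-force event-by-event oracle", {
  a <- 0.007; x <- 16
  oracle <- brute_force_flood(a, x, npix = 900, duration = 1, seed = 5)
  sim <- simulate_flat_movie(spec0, scene_uniform(30, x), 1, seed = 6)
  st <- gt_rate(sim)
  closed <- (1 - exp(-a * x)) / a
  expect_equal(closed, 15.136, tolerance = 1e-3)
  expect_lt(abs(oracle$rate - closed), 3 * oracle$rate_se)
  expect_lt(abs(st$rate - closed), 3 * st$se)
  expect_lt(abs(st$rate - oracle$rate), 3 * sqrt(st$se^2 + oracle$rate_se^2))
  # the oracle's emitted totals are Poisson with the same mean
  expect_lt(abs(mean(oracle$emitted) - x * round(1 / a) * a),
            3 * sd(oracle$emitted) / sqrt(900))
})

test_that("detected rate is monotone in x, linear as a -> 0, bounded by 1/a", {
  rates <- vapply(c(5, 20, 50, 78), function(x) {
    gt_rate(simulate_flat_movie(spec0, scene_uniform(128, x), 1, seed = 7))$rate
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_true(all(rates < 1 / 0.007))
  tiny_a <- detector_spec(a = 1e-4, false_positive_rate = 0, frame_period = 1)
  r <- gt_rate(simulate_flat_movie(tiny_a, scene_uniform(128, 50), 1, seed = 8))
  expect_lt(abs(r$rate - 50), max(3 * r$se, 0.05))
})

test_that("the same seed reproduces movie and ground truth bit for bit", {
  sc <- scene_uniform(64, 30)
  s1 <- simulate_flat_movie(spec0, sc, 1, seed = 33)
  s2 <- simulate_flat_movie(spec0, sc, 1, seed = 33)
  expect_identical(s1$movie$data, s2$movie$data)
  expect_identical(s1$ground_truth, s2$ground_truth)
  # skipping ground truth must not change the movie stream
  s3 <- simulate_flat_movie(spec0, sc, 1, seed = 33, ground_truth = FALSE)
  expect_identical(s1$movie$data, s3$movie$data)
  s4 <- simulate_flat_movie(spec0, sc, 1, seed = 34)
  expect_false(identical(s1$movie$data, s4$movie$data))
})

test_that("every nonzero super-res value is a multiple of the electron value", {
  sim <- simulate_flat_movie(detector_spec(a = 0.007, false_positive_rate = 1e-3,
                                           frame_period = 0.2),
                             scene_uniform(64, 60), 1, seed = 2)
  v <- sim$movie$data[sim$movie$data != 0]
  expect_true(length(v) > 0)
  expect_true(all(v %% 16 == 0))
})

test_that("input rates above saturation are refused", {
  expect_error(simulate_flat_movie(spec0, scene_uniform(32, 90), 1, seed = 1),
               class = "detchar_saturated")
  expect_error(simulate_edge_movie(spec0, 5, 0, base_input_eps = 90,
                                   duration = 1, seed = 1),
               class = "detchar_saturated")
})

test_that("frame assignment follows window start times", {
  spec <- detector_spec(a = 0.01, false_positive_rate = 0, frame_period = 0.25)
  sim <- simulate_flat_movie(spec, scene_uniform(32, 50), 1, seed = 9)
  expect_equal(n_frames(sim$movie), 4L)
  expect_equal(sim$movie$exposure_time, 1, tolerance = 1e-9)
  # each frame holds 25 windows of expected rate y * a each
  per_frame <- apply(sim$movie$data, 3, sum) / 16 / 32^2
  y <- (1 - exp(-0.01 * 50)) / 0.01
  expect_equal(mean(per_frame), y * 0.25, tolerance = 0.05)
})

test_that("beam-off simulation carries only false positives at the set rate", {
  silent <- simulate_beam_off(detector_spec(false_positive_rate = 0), 32, 5, seed = 1)
  expect_true(all(silent$data == 0))
  spec <- detector_spec(false_positive_rate = 1e-3, frame_period = 1)
  mov <- simulate_beam_off(spec, 128, 50, seed = 4)
  est <- false_positive_rate_estimate(mov)
  expected_events <- 1e-3 * 128^2 * 50
  se <- sqrt(expected_events)
  expect_lt(abs(est * 128^2 * 50 - expected_events), 3 * se)
})

test_that("edge movies put only false positives on the dark side", {
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, psf_sigma = 0,
                        frame_period = 1)
  mov <- simulate_edge_movie(spec, edge_angle = 5, base_input_eps = 12,
                             duration = 2, seed = 11, shape = c(96, 96))
  img <- bin_to_physical(mov)
  expect_true(all(img[, 1:30] == 0))
  expect_gt(mean(img[, 66:96]), 12 * 2 * 0.9)
  expect_error(simulate_edge_movie(spec, 0.2, 0, 12, 1, seed = 1),
               class = "detchar_edge_angle")
  expect_error(simulate_edge_movie(spec, 30, 0, 12, 1, seed = 1),
               class = "detchar_edge_angle")
})

test_that("edge offset moves the recovered edge position accordingly", {
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, psf_sigma = 0.4,
                        frame_period = 10)
  m0 <- simulate_edge_movie(spec, 5, 0, 12, 87, seed = 12, shape = c(192, 96))
  m1 <- simulate_edge_movie(spec, 5, 0.5, 12, 87, seed = 12, shape = c(192, 96))
  e0 <- fit_edge(bin_to_physical(m0))
  e1 <- fit_edge(bin_to_physical(m1))
  mid0 <- e0$intercept + e0$slope * (96 - 1)
  mid1 <- e1$intercept + e1$slope * (96 - 1)
  expect_equal(mid1 - mid0, 0.5, tolerance = 0.15)
})

test_that("reslog tables round-trip through the fit for every transform", {
  for (tr in c("reciprocal", "identity", "reciprocal_squared")) {
    intercept <- if (tr == "identity") 4 else 0.27
    slope <- if (tr == "identity") -0.4 else 0.063
    tab <- simulate_reslog_table(slope, intercept, c(1e4, 1e5, 1e6), 0,
                                 transform = tr, seed = 1)
    fit <- fit_reslog(tab, transform = tr)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  expect_error(simulate_reslog_table(0.1, -2, c(10, 100), 0, seed = 1),
               class = "detchar_bad_transform")
})
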