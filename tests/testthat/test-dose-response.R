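test_that("intensity conversion follows the counts-to-eps rule", {
  zero <- superres_movie(array(0L, c(8, 8, 2)), 1 / 60, 1)
  expect_equal(intensity_to_detected_eps(zero), 0)
  # mean super-res intensity 60 over 1 s -> 60 / 16 * 4 = 15 eps
  m <- superres_movie(array(60, c(16, 16, 1)), 1, 1)
  expect_equal(intensity_to_detected_eps(m), 15)
  # one electron (value 16) in every super-res pixel over 1 s -> 4 eps
  m <- superres_movie(array(16L, c(16, 16, 1)), 1, 1)
  expect_equal(intensity_to_detected_eps(m), 4)
})

test_that("dose ladders scale input with pixel area under constant flux", {
  one <- data.frame(magnification = 100000, pixel_size = 0.6,
                    mean_detected_eps = 9)
  expect_equal(build_dose_ladder(one)$input_eps, 9)
  two <- data.frame(magnification = c(120000, 60000),
                    pixel_size = c(0.5, 1.0),
                    mean_detected_eps = c(10, 35))
  lad <- build_dose_ladder(two)
  expect_equal(lad$input_eps, c(10, 40))
  expect_equal(lad$detected_eps, c(10, 35))
  expect_error(build_dose_ladder(rbind(two, two[1, ])), class = "detchar_bad_arg")
  odd <- data.frame(magnification = c(1e5, 5e4), pixel_size = c(1.0, 0.5),
                    mean_detected_eps = c(5, 6))
  expect_warning(build_dose_ladder(odd), class = "detchar_nonmonotonic")
})

test_that("simulated magnification ladders recover the true input rates", {
  # constant specimen flux: x scales with pixel area; anchor CL negligible
  spec <- detector_spec(a = 0.007, false_positive_rate = 0, frame_period = 1)
  px <- c(0.5, 0.75, 1.0)
  x_true <- 5 * (px / 0.5)^2
  detected <- vapply(seq_along(px), function(i) {
    sim <- simulate_flat_movie(spec, scene_uniform(256, x_true[i]), 1,
                               seed = 40 + i, ground_truth = FALSE)
    intensity_to_detected_eps(sim$movie)
  }, numeric(1))
  lad <- build_dose_ladder(data.frame(magnification = c(3, 2, 1) * 1e4,
                                      pixel_size = px,
                                      mean_detected_eps = detected))
  expect_equal(lad$input_eps, x_true, tolerance = 0.02)
})

test_that("anchor correction moves ladder inputs toward the true rates", {
  a <- 0.007
  px <- c(0.5, 0.8, 1.1)
  x_true <- 20 * (px / 0.5)^2
  ser <- data.frame(magnification = c(3, 2, 1) * 1e4, pixel_size = px,
                    mean_detected_eps = predict_detected(a, x_true))
  naive <- build_dose_ladder(ser)
  corrected <- build_dose_ladder(ser, correct_anchor = TRUE)
  expect_true(all(naive$input_eps < x_true))  # anchor bias is downward
  expect_true(all(abs(corrected$input_eps - x_true) <
                    abs(naive$input_eps - x_true)))
})

test_that("least-squares fit to the measured ladder reproduces the printed dose response", {
  m <- fit_dose_response(measured_pairs())
  expect_equal(m$a, 0.0071, tolerance = 0.01)
  # detected rates at the measured inputs round back to the printed values
  expect_equal(round(predict_detected(m, c(16, 34, 78))), c(15, 30, 60))
  expect_equal(round(100 * coincidence_loss(m, c(15, 30, 66))), c(5, 10, 20))
  expect_equal(round(invert_detected(m, 12), 1), 12.5)
  expect_equal(round(invert_detected(m, 15)), 16)
})

test_that("noiseless curve samples recover a to optimizer tolerance", {
  for (a in c(1e-4, 1e-3, 0.007, 0.02, 0.05)) {
    x <- c(2, 10, 25, 50, 75)
    pairs <- data.frame(input_eps = x, detected_eps = (1 - exp(-a * x)) / a)
    fit <- fit_dose_response(pairs)
    expect_equal(fit$a, a, tolerance = 1e-4)
    expect_lt(fit$residual_rms, 1e-5)
  }
})

test_that("fit on a lossless ladder warns about the lower bound", {
  pairs <- data.frame(input_eps = c(5, 10), detected_eps = c(5, 10))
  expect_warning(fit_dose_response(pairs), class = "detchar_no_loss")
})

test_that("predict and invert are exact inverses below saturation", {
  m <- fit_dose_response(measured_pairs())
  x <- c(0.01, 1, 15, 60, 120)
  expect_equal(invert_detected(m, predict_detected(m, x)), x, tolerance = 1e-9)
  y <- c(5, 50, 100, 140)
  expect_equal(predict_detected(m, invert_detected(m, y)), y, tolerance = 1e-9)
  expect_error(invert_detected(m, saturation_limit(m)),
               class = "detchar_above_saturation")
})

test_that("coincidence loss is 0 at 0, strictly increasing, approaching 1", {
  m <- fit_dose_response(measured_pairs())
  expect_equal(coincidence_loss(m, 0), 0)
  x <- c(1e-6, 0.1, 1, 10, 100, 1e4)
  cl <- coincidence_loss(m, x)
  expect_true(all(diff(cl) > 0))
  expect_lt(cl[1], 1e-5)
  expect_gt(cl[length(cl)], 0.98)
  # linearity limit: y/x -> 1
  expect_equal(predict_detected(m, 1e-8) / 1e-8, 1, tolerance = 1e-6)
})

test_that("saturation limit is the reciprocal of a", {
  expect_equal(saturation_limit(0.007), 1 / 0.007)
  expect_equal(saturation_limit(0.01), 100)
  m <- fit_dose_response(measured_pairs())
  expect_true(all(predict_detected(m, c(10, 100, 1e3)) < saturation_limit(m)))
})

test_that("end-to-end simulated characterization recovers a within 5 percent", {
  a_true <- 0.007
  spec <- detector_spec(a = a_true, false_positive_rate = 0, frame_period = 1)
  x <- c(5, 15, 30, 60, 78)
  detected <- vapply(seq_along(x), function(i) {
    sim <- simulate_flat_movie(spec, scene_uniform(384, x[i]), 1,
                               seed = 50 + i, ground_truth = FALSE)
    intensity_to_detected_eps(sim$movie)
  }, numeric(1))
  fit <- fit_dose_response(data.frame(input_eps = x, detected_eps = detected))
  expect_lt(abs(fit$a - a_true) / a_true, 0.05)
})

test_that("exposure planning reproduces the dose-rate ladder frame counts", {
  # the three characterized exposures at a fixed 60 fps movie rate
  expect_equal(frames_for_exposure(c(1.264, 0.666, 0.333), 60), c(76L, 40L, 20L))
  exact <- plan_exposure(60, 1, 60, 60)
  expect_equal(exact$exposure_time, 1)
  expect_equal(exact$n_frames, 60L)
  expect_equal(exact$achieved_dose, 60)
  # dose, time and frames stay mutually consistent after rounding
  p <- plan_exposure(60, 0.599, 15, 60)
  expect_equal(p$n_frames, frames_for_exposure(p$exposure_time, 60))
  expect_equal(p$achieved_dose, p$n_frames / 60 * 15 / 0.599^2)
})

test_that("specimen dose rate arithmetic matches the characterization conditions", {
  expect_equal(specimen_dose_rate(12, 0.6), 12 / 0.36)
  expect_equal(round(specimen_dose_rate(12, 0.6)), 33)
  total <- specimen_dose_rate(15, 0.599) * 1.347
  expect_equal(total, 56.3, tolerance = 1e-2)
  expect_equal(specimen_dose_rate(7, 1), 7)
})

test_that("false-positive percentage is negligible at low dose rates", {
  expect_equal(false_positive_percent(2.86e-6, 0.1), 0.00286)
  expect_lt(false_positive_percent(2.86e-6, 0.1), 0.003)
  expect_equal(false_positive_percent(0, 5), 0)
  expect_equal(false_positive_percent(1e-4, 1), 0.01)
})
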