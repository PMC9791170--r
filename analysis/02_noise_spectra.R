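#!/usr/bin/env Rscript
# Noise-power-spectrum analysis of simulated flood exposures.
#
# Computes tile-averaged rotationally averaged power spectra, normalized
# between 1.5x and 2.0x physical Nyquist, at several dose rates; shows the
# low-frequency suppression growing with dose rate and compares the
# NPS-based coincidence-loss estimate (dead-time mapping of the 0.06-0.08
# physical-Nyquist band deficit) with the dose-response model.

suppressPackageStartupMessages(library(detchar))
dir.create("results", showWarnings = FALSE)
seed <- 1L

a <- 0.007
spec <- detector_spec(a = a, false_positive_rate = 0, frame_period = 1)
rates <- c(0.1, 16, 34, 78)

curves <- list(); summary_rows <- list()
for (x in rates) {
  acc <- NULL
  n_tiles <- 16
  for (t in seq_len(n_tiles)) {
    sim <- simulate_flat_movie(spec, scene_uniform(512, x), 1,
                               seed = seed + 1000 * match(x, rates) + t,
                               ground_truth = FALSE)
    sp <- radial_power_spectrum(sim$movie, n_bins = 256)
    if (is.null(acc)) acc <- sp else acc$power <- acc$power + sp$power
  }
  acc$power <- acc$power / n_tiles
  nn <- normalize_nps(acc)
  curves[[as.character(x)]] <- data.frame(input_eps = x, freq = nn$freq,
                                          nnps = nn$power)
  summary_rows[[as.character(x)]] <- data.frame(
    input_eps = x,
    suppression = nps_coincidence_loss(nn, method = "suppression"),
    cl_nps = nps_coincidence_loss(nn, method = "dead_time"),
    cl_model = coincidence_loss(a, x)
  )
}
curve_tab <- do.call(rbind, curves)
sum_tab <- do.call(rbind, summary_rows)
write.csv(curve_tab, "results/nnps_curves.csv", row.names = FALSE)
write.csv(sum_tab, "results/nps_coincidence_loss.csv", row.names = FALSE)
cat("NPS-based coincidence loss versus the dose-response model:\n")
print(transform(sum_tab,
                suppression = round(suppression, 3),
                cl_nps = round(cl_nps, 3),
                cl_model = round(cl_model, 3)), row.names = FALSE)
cat("\nLow-frequency suppression rises with dose rate; the dead-time mapping\n")
cat("of the band deficit tracks the model loss, while the raw deficit is\n")
cat("about twice the loss at low rates (a*y versus CL). At ultra-low rates\n")
cat("(0.1 eps) the spectrum is white and any apparent deficit is sampling\n")
cat("noise in the rotational average, which is why precise loss figures come\n")
cat("from the dose-response fit rather than the spectra.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  p <- ggplot(curve_tab, aes(freq, nnps, colour = factor(input_eps))) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    coord_cartesian(ylim = c(0, 1.3)) +
    labs(x = "spatial frequency (physical Nyquist)", y = "NNPS",
         colour = "input eps") +
    theme_minimal()
  ggsave("results/figures/nnps_curves.png", p, width = 7, height = 4, dpi = 150)
}
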