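#!/usr/bin/env Rscript
# ResLog analysis: resolution versus log10(particle count).
#
# Reproduces the slope comparison between the three dose-rate datasets from
# the recorded slopes, and demonstrates the full fit machinery on synthetic
# tables with known parameters (the reciprocal-resolution transform is the
# package default and is recorded in every fit).

suppressPackageStartupMessages(library(detchar))
dir.create("results", showWarnings = FALSE)

slopes <- read.csv(system.file("extdata", "reslog_slopes.csv", package = "detchar"))
ref <- slopes$slope[1]
slopes$pct_worse <- vapply(slopes$slope, function(s) slope_percent_change(ref, s),
                           numeric(1))
cat("ResLog slopes by detected dose rate (reference: 15 eps):\n")
print(transform(slopes, pct_worse = round(pct_worse, 1)), row.names = FALSE)
cat("\nThe slope degrades by ~8% at 30 eps and ~15% at 60 eps: higher\n")
cat("coincidence loss lowers the information contributed per particle.\n\n")
write.csv(slopes, "results/reslog_slope_comparison.csv", row.names = FALSE)

# Synthetic round trip + particle budgets under a stated transform. The
# printed slopes' units/transform are not recorded with the measurements,
# so particle-factor projections are only made on synthetic fits whose
# transform is known.
fits <- lapply(seq_len(nrow(slopes)), function(i) {
  tab <- simulate_reslog_table(slopes$slope[i], intercept = 0.27 - 0.01 * i,
                               particle_counts = 10^seq(3.5, 5.5, by = 0.5),
                               noise_sd = 0.002, seed = 100 + i)
  fit_reslog(tab)
})
cat("Synthetic fits (reciprocal transform):\n")
for (i in seq_along(fits)) {
  cat(sprintf("  %d detected eps: slope %.4f (true %.4f), r^2 = %.4f\n",
              slopes$detected_eps[i], fits[[i]]$slope, slopes$slope[i],
              fits[[i]]$r_squared))
}
target <- 1.8
factors <- vapply(fits, function(f)
  suppressWarnings(particle_factor(fits[[1]], f, target)), numeric(1))
cat(sprintf("\nParticles needed for %.1f A, relative to the 15 eps line: %s\n",
            target, paste(sprintf("%.2fx", factors), collapse = ", ")))
write.csv(data.frame(detected_eps = slopes$detected_eps,
                     fitted_slope = vapply(fits, `[[`, numeric(1), "slope"),
                     particle_factor_at_1.8A = factors),
          "results/reslog_synthetic_fits.csv", row.names = FALSE)
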