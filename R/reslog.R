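# ResLog analysis: resolution versus the logarithm of particle number.
# The slope reflects per-particle information content; the intercept (the
# extrapolated resolution from a single particle) reflects alignability.

reslog_transforms <- list(
  identity = list(
    forward = function(res) res,
    inverse = function(t) t
  ),
  reciprocal = list(
    forward = function(res) 1 / res,
    inverse = function(t) 1 / t
  ),
  reciprocal_squared = list(
    forward = function(res) 1 / res^2,
    inverse = function(t) 1 / sqrt(t)
  )
)

get_reslog_transform <- function(transform) {
  if (!transform %in% names(reslog_transforms)) {
    stop_detchar(sprintf("unknown transform '%s' (use %s)", transform,
                         paste(names(reslog_transforms), collapse = ", ")),
                 "bad_transform")
  }
  reslog_transforms[[transform]]
}

#' Fit a ResLog line
#'
#' Ordinary least squares of the transformed resolution on
#' `log10(n_particles)`. The transform is a mandatory, recorded part of the
#' fit: published ResLog slopes are only comparable under the same stated
#' transform. Default is reciprocal resolution (Angstrom^-1), so better
#' resolution from more particles gives a positive slope.
#'
#' @param points `data.frame` with columns `n_particles` (`>= 1`) and
#'   `resolution` (Angstrom, `> 0`); at least two distinct particle counts.
#' @param transform `"reciprocal"` (default), `"identity"`, or
#'   `"reciprocal_squared"`.
#' @return Object of class `reslog_fit`: `slope`, `intercept`, `transform`,
#'   `r_squared`, `n_range`.
#' @examples
#' tab <- simulate_reslog_table(0.063, 0.27, c(1e4, 1e5, 1e6), 0, seed = 1)
#' fit_reslog(tab)$slope
#' @export
fit_reslog <- function(points, transform = "reciprocal") {
  if (!all(c("n_particles", "resolution") %in% names(points))) {
    stop_detchar("points needs columns n_particles and resolution", "bad_arg")
  }
  if (any(points$n_particles < 1)) stop_detchar("n_particles must be >= 1", "bad_arg")
  if (any(points$resolution <= 0)) stop_detchar("resolutions must be > 0", "bad_arg")
  if (length(unique(points$n_particles)) < 2) {
    stop_detchar("need >= 2 points with distinct particle counts", "bad_arg")
  }
  tr <- get_reslog_transform(transform)
  xx <- log10(points$n_particles)
  yy <- tr$forward(points$resolution)
  fit <- stats::lm(yy ~ xx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((yy - mean(yy))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         transform = transform,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         n_range = range(points$n_particles)),
    class = "reslog_fit"
  )
}

#' @export
print.reslog_fit <- function(x, ...) {
  cat(sprintf("<reslog_fit> slope %.4g, intercept %.4g (%s transform), r^2 = %.4f\n",
              x$slope, x$intercept, x$transform, x$r_squared))
  invisible(x)
}

#' Relative slope change between two ResLog fits
#'
#' `100 * (slope_ref - slope_other) / slope_ref`: positive when the other
#' dataset's slope is worse (smaller information gain per decade of
#' particles).
#'
#' @param fit_ref,fit_other [fit_reslog()] results (or bare slopes) sharing
#'   the same transform.
#' @return Percent change.
#' @examples
#' slope_percent_change(0.063, 0.058)
#' @export
slope_percent_change <- function(fit_ref, fit_other) {
  s1 <- if (inherits(fit_ref, "reslog_fit")) fit_ref$slope else fit_ref
  s2 <- if (inherits(fit_other, "reslog_fit")) fit_other$slope else fit_other
  if (inherits(fit_ref, "reslog_fit") && inherits(fit_other, "reslog_fit") &&
      fit_ref$transform != fit_other$transform) {
    stop_detchar("fits use different resolution transforms; not comparable", "bad_arg")
  }
  if (s1 == 0) stop_detchar("zero reference slope", "bad_arg")
  100 * (s1 - s2) / s1
}

#' Particle budget for a target resolution
#'
#' Inverts the fitted ResLog line:
#' `n = 10^((transform(target) - intercept) / slope)`. Extrapolation more
#' than 10x beyond the fitted particle-count range triggers a warning (the
#' line is empirical, not a physical law).
#'
#' @param fit A [fit_reslog()] result.
#' @param target_resolution Target resolution, Angstrom.
#' @return Required particle count.
#' @export
particles_for_resolution <- function(fit, target_resolution) {
  stopifnot(inherits(fit, "reslog_fit"))
  check_scalar(target_resolution, "target_resolution", positive = TRUE)
  tr <- get_reslog_transform(fit$transform)
  t_target <- tr$forward(target_resolution)
  if (fit$slope == 0) stop_detchar("zero slope; target unreachable", "unreachable")
  n <- 10^((t_target - fit$intercept) / fit$slope)
  if (!is.null(fit$n_range) &&
      (n > 10 * fit$n_range[2] || n < fit$n_range[1] / 10)) {
    warn_detchar(sprintf("target needs %.3g particles, >10x beyond fitted range", n),
                 "extrapolation")
  }
  n
}

#' @rdname particles_for_resolution
#' @param fit_a,fit_b Two [fit_reslog()] results sharing a transform.
#' @return `particle_factor()`: the ratio `n_b / n_a` of particles needed
#'   by dataset b versus dataset a to reach the target.
#' @export
particle_factor <- function(fit_a, fit_b, target_resolution) {
  if (fit_a$transform != fit_b$transform) {
    stop_detchar("fits use different resolution transforms; not comparable", "bad_arg")
  }
  na <- particles_for_resolution(fit_a, target_resolution)
  nb <- particles_for_resolution(fit_b, target_resolution)
  nb / na
}
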