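#' Sinusoidal illumination pattern set
#'
#' Describes the excitation fringes of a 2-angle-3-phase or 3-angle-3-phase
#' acquisition: pattern orientations, fringe period, the per-(angle, phase)
#' illumination phases, modulation depth and amplitude. The k-vector of
#' angle `theta` is `(sin(theta), cos(theta)) / period` in cycles/pixel
#' (rows down, columns right), so `|k| = 1/period`.
#'
#' @param n_angles 2 or 3 pattern orientations.
#' @param angles orientations in degrees; adjacent angles must differ by 90
#'   (2 angles) or 60 (3 angles) degrees up to a small deviation. Defaults:
#'   35/125 and 35/95/155.
#' @param period fringe period in pixels.
#' @param phases optional `n_angles x 3` matrix of illumination phases
#'   (radians); default nominal steps `0, 2pi/3, 4pi/3` for every angle.
#' @param modulation fringe modulation depth `m` in `[0, 1]`.
#' @param amplitude peak illumination amplitude `I0` (photons per unit
#'   scene intensity and exposure).
#' @return object of class `pattern_set`.
#' @examples
#' pattern_set(2, period = 3.9)
#' @export
pattern_set <- function(n_angles = 2L, angles = NULL, period = 3.9,
                        phases = NULL, modulation = 0.8, amplitude = 1) {
  n_angles <- as.integer(n_angles)
  stopifnot(n_angles %in% c(2L, 3L), period > 0,
            modulation >= 0, modulation <= 1, amplitude > 0)
  if (is.null(angles))
    angles <- if (n_angles == 2L) c(35, 125) else c(35, 95, 155)
  stopifnot(length(angles) == n_angles)
  nominal_step <- if (n_angles == 2L) 90 else 60
  if (n_angles > 1 && any(abs(diff(angles) - nominal_step) > 5))
    stop("adjacent pattern angles must differ by ", nominal_step,
         " degrees (within 5)")
  if (is.null(phases))
    phases <- matrix(rep(c(0, 2 * pi / 3, 4 * pi / 3), each = n_angles),
                     n_angles, 3)
  stopifnot(is.matrix(phases), nrow(phases) == n_angles, ncol(phases) == 3)
  th <- angles * pi / 180
  k_vectors <- cbind(ky = sin(th), kx = cos(th)) / period
  structure(list(n_angles = n_angles, n_phases = 3L, angles = angles,
                 period = period, k_vectors = k_vectors, phases = phases,
                 modulation = modulation, amplitude = amplitude),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("Pattern set: %d angles x 3 phases, period %.3f px (|k| = %.4f c/px), m = %.2f\n",
              x$n_angles, x$period, 1 / x$period, x$modulation))
  cat("  angles (deg):", paste(signif(x$angles, 4), collapse = ", "), "\n")
  invisible(x)
}

# Illumination field I0/2 * (1 + m cos(2 pi k.r + phi)) on an image grid.
illumination_field <- function(pattern, shape, angle, phase) {
  cg <- coord_grids(shape[1], shape[2])
  k <- pattern$k_vectors[angle, ]
  phi <- pattern$phases[angle, phase]
  pattern$amplitude / 2 *
    (1 + pattern$modulation * cos(2 * pi * (k[1] * cg$y + k[2] * cg$x) + phi))
}
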