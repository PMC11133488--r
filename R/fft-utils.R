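# Fourier helpers shared by the simulator and the reconstruction pipeline.
#
# Conventions (fixed package-wide):
#   * images are numeric matrices indexed [row, col] = [y, x], origin top-left;
#   * spatial coordinates are 0-based pixel offsets (x along columns);
#   * spatial frequencies are in cycles/pixel, DC at [1, 1] unless a function
#     says "centered" (then DC sits at floor(dim/2) + 1);
#   * all spectrum shifts are spatial phase ramps, exact for non-integer k.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Discrete Fourier frequencies
#'
#' Frequencies (cycles/pixel) of the unshifted FFT bins along one axis.
#'
#' @param n number of samples.
#' @return numeric vector of length `n` in `[-0.5, 0.5)` ordering DC first.
#' @keywords internal
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k < ceiling(n / 2), k, k - n) / n
}

#' @keywords internal
fftshift <- function(x) {
  if (is.matrix(x)) {
    s <- floor(dim(x) / 2)
    x[c(seq_len(dim(x)[1])[-seq_len(s[1])], seq_len(s[1])),
      c(seq_len(dim(x)[2])[-seq_len(s[2])], seq_len(s[2]))]
  } else {
    s <- floor(length(x) / 2)
    x[c(seq_along(x)[-seq_len(s)], seq_len(s))]
  }
}

#' @keywords internal
ifftshift <- function(x) {
  if (is.matrix(x)) {
    s <- ceiling(dim(x) / 2)
    x[c(seq_len(dim(x)[1])[-seq_len(s[1])], seq_len(s[1])),
      c(seq_len(dim(x)[2])[-seq_len(s[2])], seq_len(s[2]))]
  } else {
    s <- ceiling(length(x) / 2)
    x[c(seq_along(x)[-seq_len(s)], seq_len(s))]
  }
}

# Frequency grids (unshifted) for an nr x nc image: list(fy, fx) matrices.
freq_grids <- function(nr, nc) {
  list(fy = matrix(fft_freq(nr), nr, nc),
       fx = matrix(fft_freq(nc), nr, nc, byrow = TRUE))
}

# 0-based coordinate grids: list(y, x) matrices.
coord_grids <- function(nr, nc) {
  list(y = matrix(seq_len(nr) - 1, nr, nc),
       x = matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE))
}

#' Sub-pixel image translation by Fourier phase ramp
#'
#' Shifts an image by `(dy, dx)` pixels (positive = toward larger row/col
#' index) by multiplying its spectrum with the corresponding phase ramp.
#' Exact for non-integer shifts; periodic boundary.
#'
#' @param image numeric matrix.
#' @param shift numeric length-2 vector `c(dy, dx)` in pixels.
#' @return shifted image (real matrix).
#' @export
fourier_translate <- function(image, shift) {
  stopifnot(is.matrix(image), length(shift) == 2, all(is.finite(shift)))
  if (all(shift == 0)) return(image)
  fg <- freq_grids(nrow(image), ncol(image))
  ramp <- exp(-2i * pi * (fg$fy * shift[1] + fg$fx * shift[2]))
  Re(ifft2(fft2(image) * ramp))
}

# Shift an unshifted spectrum G(k) -> G(k + k0), k0 = c(ky, kx) cycles/pixel,
# implemented as F[ F^-1(G)(r) * exp(-2i*pi*(k0 . r)) ].
shift_spectrum <- function(spec, k0) {
  if (all(k0 == 0)) return(spec)
  cg <- coord_grids(nrow(spec), ncol(spec))
  fft2(ifft2(spec) * exp(-2i * pi * (k0[1] * cg$y + k0[2] * cg$x)))
}

# Zero-pad an unshifted N x M spectrum onto the 2N x 2M grid (values scaled
# by 4 so real-space intensities are preserved on the finer grid).
upsample_spectrum <- function(spec) {
  d <- dim(spec)
  out <- matrix(0 + 0i, 2L * d[1], 2L * d[2])
  sh <- fftshift(spec)
  r0 <- floor(d[1] / 2); c0 <- floor(d[2] / 2)
  out[(d[1] - r0 + 1):(d[1] - r0 + d[1]), (d[2] - c0 + 1):(d[2] - c0 + d[2])] <- sh
  ifftshift(out) * 4
}

# Radial frequency magnitude grid (unshifted), cycles/pixel.
freq_radius <- function(nr, nc) {
  fg <- freq_grids(nr, nc)
  sqrt(fg$fy^2 + fg$fx^2)
}
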