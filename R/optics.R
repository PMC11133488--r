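#' Optical system description
#'
#' Collects the physical parameters that determine the detection OTF: the
#' objective numerical aperture, emission/excitation wavelengths and the
#' camera pixel size in sample space. The incoherent cutoff is
#' `k_c = 2 NA / lambda_em`; expressed in cycles/pixel it must stay below
#' the Nyquist limit 0.5 for the model to be sampled correctly.
#'
#' @param na numerical aperture (0, 1.7].
#' @param wavelength_em emission wavelength, nm.
#' @param wavelength_ex excitation wavelength, nm.
#' @param pixel_size sample-space pixel size, nm.
#' @return an object of class `optics_model`.
#' @examples
#' op <- optics_model(na = 1.49, wavelength_em = 580, pixel_size = 65)
#' cutoff_frequency(op)  # cycles/pixel
#' @export
optics_model <- function(na = 1.49, wavelength_em = 580, wavelength_ex = 561,
                         pixel_size = 65) {
  stopifnot(na > 0, na <= 1.7,
            wavelength_em > 300, wavelength_em < 800,
            wavelength_ex > 300, wavelength_ex < 800,
            pixel_size > 0)
  obj <- structure(list(na = na, wavelength_em = wavelength_em,
                        wavelength_ex = wavelength_ex, pixel_size = pixel_size),
                   class = "optics_model")
  if (cutoff_frequency(obj) >= 0.5) {
    stop("OTF cutoff ", signif(cutoff_frequency(obj), 4),
         " cycles/pixel is at or above the Nyquist limit 0.5; ",
         "reduce pixel size or NA (undersampled optics model)")
  }
  obj
}

#' @export
print.optics_model <- function(x, ...) {
  cat("Optics: NA", x$na, " em", x$wavelength_em, "nm  ex", x$wavelength_ex,
      "nm  pixel", x$pixel_size, "nm  cutoff",
      signif(cutoff_frequency(x), 4), "cycles/pixel\n")
  invisible(x)
}

#' Incoherent cutoff frequency in cycles/pixel
#' @param optics an [optics_model()].
#' @export
cutoff_frequency <- function(optics) {
  2 * optics$na / optics$wavelength_em * optics$pixel_size
}

# Ideal incoherent OTF of a circular pupil (autocorrelation of the pupil),
# as a function of normalized radial frequency rho = |k| / k_c.
otf_radial <- function(rho) {
  v <- numeric(length(rho))
  inside <- rho < 1
  r <- pmin(rho[inside], 1)
  v[inside] <- (2 / pi) * (acos(r) - r * sqrt(1 - r^2))
  v
}

# Unshifted OTF sampled at frequencies (fy + k_off[1], fx + k_off[2]); the
# offset form evaluates H(k + k_theta) for shifted spectral orders.
otf_matrix <- function(optics, shape, k_off = c(0, 0)) {
  fg <- freq_grids(shape[1], shape[2])
  kc <- cutoff_frequency(optics)
  rho <- sqrt((fg$fy + k_off[1])^2 + (fg$fx + k_off[2])^2) / kc
  matrix(otf_radial(rho), shape[1], shape[2])
}

#' Diffraction-limited OTF on an image grid
#'
#' Samples the ideal incoherent OTF of a circular pupil on the frequency grid
#' of an image, DC-centered (value 1 at the center bin, 0 at and beyond the
#' cutoff `2 NA / lambda_em`).
#'
#' @param optics an [optics_model()].
#' @param shape integer vector `c(rows, cols)`, at least 16 x 16.
#' @return real matrix in `[0, 1]`, DC at `floor(shape/2) + 1`.
#' @examples
#' otf <- make_otf(optics_model(), c(64, 64))
#' otf[33, 33]  # 1 at DC
#' @export
make_otf <- function(optics, shape) {
  stopifnot(inherits(optics, "optics_model"),
            length(shape) == 2, all(shape >= 16))
  fftshift(otf_matrix(optics, as.integer(shape)))
}

# Real-space PSF (sum 1, centered at floor(dim/2)+1) from the analytic OTF.
psf_from_optics <- function(optics, shape) {
  h <- otf_matrix(optics, shape)
  psf <- fftshift(Re(ifft2(h)))
  psf <- pmax(psf, 0)
  psf / sum(psf)
}
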