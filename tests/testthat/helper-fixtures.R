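# Shared fixtures: built once per test run, small enough to stay fast.

fx_optics <- optics_model(na = 1.49, wavelength_em = 580, wavelength_ex = 561,
                          pixel_size = 65)

# wrap an angle difference into (-pi, pi]
wrap_rad <- function(x) ((x + pi) %% (2 * pi)) - pi

rel_frob <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# analytic forward components S(k)H, S(k -+ k0)H of a noiseless render
forward_components <- function(scene, optics, k) {
  shp <- dim(scene)
  h <- parsim:::otf_matrix(optics, shp)
  cg <- parsim:::coord_grids(shp[1], shp[2])
  ramp <- exp(2i * pi * (k[1] * cg$y + k[2] * cg$x))
  list(order0 = parsim:::fft2(unclass(scene)) * h,
       minus = parsim:::fft2(unclass(scene) * ramp) * h,
       plus = parsim:::fft2(unclass(scene) / ramp) * h)
}

# noiseless stack reused by several estimation tests; 192 rows matches the
# instrument's full sub-ROI height and gives the estimators the spectral
# support their accuracy targets assume
fx_stack_noiseless <- simulate_sim_stack(seed = 3, snr_db = NA, n_angles = 2,
                                         shape = c(192, 192),
                                         phase_jitter_sd = 0.3)
fx_width <- 192
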