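# Reconstruction: order shifting, fusion, synthesized PSF, end-to-end
# estimator object, rolling mode.

test_that("spectral order shifting is exact, invertible and energy-conserving", {
  set.seed(5)
  img <- matrix(stats::rnorm(64^2), 64)
  sp <- parsim:::fft2(img)
  k <- c(0.071, -0.033)
  sh <- shift_order(sp, k)
  expect_equal(sum(Mod(sh)^2), sum(Mod(sp)^2), tolerance = 1e-10)
  back <- shift_order(sh, -k)
  expect_lt(rel_frob(back, sp), 1e-10)
  expect_equal(shift_order(sp, c(0, 0)), sp)
  # integer-bin shift equals circular relabeling of frequency bins
  ki <- c(3 / 64, -5 / 64)
  shi <- shift_order(sp, ki)
  rolled <- sp[c(4:64, 1:3), c(60:64, 1:59)]
  expect_lt(rel_frob(shi, rolled), 1e-10)
  expect_error(shift_order(sp, c(0.6, 0.6)), "range")
})

test_that("fusion has the extended support, sane DC and Wiener limit", {
  opf <- optics_model(pixel_size = 65 / 2)  # fine-grid optics
  shp <- c(128, 128)
  set.seed(8)
  base <- parsim:::fft2(matrix(stats::runif(prod(shp)), shp[1]))
  k <- c(0.08, 0.1)
  comps <- list(
    list(spectrum = base, k_shift = c(0, 0), m = 1),
    list(spectrum = shift_order(base, k), k_shift = k, m = 0.8),
    list(spectrum = shift_order(base, -k), k_shift = -k, m = 0.8))
  fz <- fuse_spectra(comps, opf)
  kc <- cutoff_frequency(opf)
  expect_equal(fz$extended_cutoff, kc + sqrt(sum(k^2)))
  kr <- parsim:::freq_radius(shp[1], shp[2])
  expect_true(all(Mod(fz$fused[kr > fz$extended_cutoff + 2 / shp[1]]) == 0))
  expect_true(all(fz$synthesized_otf >= 0 & fz$synthesized_otf <= 1))
  expect_equal(fz$synthesized_otf[1, 1], 1)

  # single zero-order component: Wiener-filtered widefield
  f1 <- fuse_spectra(list(list(spectrum = base, k_shift = c(0, 0), m = 1)),
                     opf, fusion_filters(apodize = FALSE))
  h <- parsim:::otf_matrix(opf, shp)
  expect_lt(rel_frob(f1$fused, h * base / (h^2 + 0.05^2)), 1e-10)
  expect_error(fuse_spectra(list(list(spectrum = base)), opf), "k_shift")
})

test_that("the synthesized PSF is centered, normalized and anisotropic", {
  res <- resolution_study(seed = 19, snr_db = 4, shape = c(96, 96),
                          n_beads = 18, final_rl_iterations = 0)
  psf <- res$recon$synthesized_psf
  ctr <- (dim(psf) + 1) / 2
  expect_equal(unname(arrayInd(which.max(psf), dim(psf))[1, ]), ctr)
  expect_equal(sum(psf), 1, tolerance = 1e-9)
  # two-angle fusion: support differs along vs between pattern angles
  ang <- res$recon$estimates[[1]]$estimate$angle
  prof <- function(theta) {
    d <- seq(0, 12, by = 0.5)
    parsim:::bilinear_sample(psf, ctr[1] + d * sin(theta * pi / 180),
                             ctr[2] + d * cos(theta * pi / 180))
  }
  along <- prof(ang); between <- prof(ang + 45)
  expect_gt(max(abs(along - between)), 1e-5 * max(psf))
})

test_that("final deconvolution reduces sidelobes without inflating flux", {
  res <- resolution_study(seed = 23, snr_db = 4, shape = c(96, 96),
                          n_beads = 18, final_rl_iterations = 0)
  sr <- res$recon$sr_image_predeconv
  psf <- res$recon$synthesized_psf
  expect_identical(final_deconvolve(sr, psf, 0), pmax(sr, 0))
  dec <- final_deconvolve(sr, psf, 10)
  expect_equal(sum(dec), sum(pmax(sr, 0)), tolerance = 1e-3)
  expect_true(all(dec >= 0))
  # first-sidelobe-to-peak ratio around the brightest bead decreases
  pk <- arrayInd(which.max(sr), dim(sr))
  ringvals <- function(img, r) {
    th <- seq(0, 2 * pi, length.out = 48)
    parsim:::bilinear_sample(img, pk[1] + r * sin(th), pk[2] + r * cos(th))
  }
  side0 <- max(ringvals(sr, 6), na.rm = TRUE) / max(sr)
  side1 <- max(ringvals(dec, 6), na.rm = TRUE) / max(dec)
  expect_lt(side1, side0)
})

test_that("end-to-end reconstruction recovers parameters and resolution on beads", {
  res <- resolution_study(seed = 11, snr_db = 4, shape = c(128, 128),
                          n_beads = 35)
  # k-vectors recovered within the params-module budget
  expect_true(all(res$estimates_error < 0.1))
  expect_gte(res$n_measured, 5)
  # resolution gain of at least 1.6x over widefield
  expect_lt(res$ratio, 1 / 1.6)
  rec <- res$recon
  expect_identical(dim(rec$sr_image), c(256L, 256L))
  expect_lt(rec$qc$imag_ratio, 0.05)
  co <- coef(rec)
  expect_identical(dim(co), c(2L, 8L))
})

test_that("a 3-angle stack consumes 9 images and recovers 60-degree spacing", {
  res <- resolution_study(seed = 31, snr_db = 4, shape = c(96, 96),
                          n_beads = 18, n_angles = 3)
  co <- coef(res$recon)
  expect_identical(nrow(co), 3L)
  d <- diff(co[, "angle_deg"])
  expect_lt(max(abs(d - 60)), 3)
})

test_that("incomplete pattern sets are rejected with a diagnostic", {
  sim <- fx_stack_noiseless
  stk5 <- subroi_stack(sim$images[1:5],
                       labels = cbind(c(1, 1, 1, 2, 2), c(1:3, 1:2)))
  expect_error(sim_reconstruct(stk5, sim$optics, c(35, 125)),
               "incomplete pattern set")
})

test_that("rolling reconstruction counts windows and matches non-rolling frames", {
  sim <- simulate_sim_stack(seed = 61, snr_db = 4, n_angles = 2,
                            shape = c(64, 64), n_beads = 60)
  imgs <- rep(sim$images, 2)   # 12 sub-images
  expect_error(rolling_reconstruct(imgs, sim$optics, c(35, 125), step = 4),
               "divide")
  roll <- suppressWarnings(
    rolling_reconstruct(imgs, sim$optics, sim$pattern_nominal$angles, step = 3,
                        final_rl_iterations = 2))
  expect_length(roll$frames, 3)  # floor((12 - 6)/3) + 1
  nonroll <- suppressWarnings(
    rolling_reconstruct(imgs, sim$optics, sim$pattern_nominal$angles, step = 6,
                        final_rl_iterations = 2))
  expect_length(nonroll$frames, 2)
  # window-aligned frames are identical
  expect_identical(roll$frames[[1]]$sr_image, nonroll$frames[[1]]$sr_image)
  expect_identical(roll$frames[[3]]$sr_image, nonroll$frames[[2]]$sr_image)
  # cadence bookkeeping: 2335 output frames over 5.73 s is the 2.45 ms step
  expect_equal(round(5730 / 2335, 2), 2.45)
})
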