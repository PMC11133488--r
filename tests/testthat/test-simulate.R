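# Forward model: OTF, raw rendering, frame assembly, dataset files.

test_that("the diffraction OTF is normalized, band-limited and matches the cutoff", {
  otf <- make_otf(fx_optics, c(64, 64))
  dc <- floor(c(64, 64) / 2) + 1
  expect_equal(otf[dc[1], dc[2]], 1)
  expect_true(all(otf >= 0 & otf <= 1))
  # closed-form cutoff: 2 NA / lambda_em in cycles/pixel
  expect_equal(cutoff_frequency(fx_optics), 2 * 1.49 / 580 * 65, tolerance = 1e-12)
  expect_equal(round(cutoff_frequency(fx_optics), 3), 0.334)
  # zero at and beyond the cutoff
  fr <- parsim:::fftshift(parsim:::freq_radius(64, 64))
  expect_true(all(otf[fr >= cutoff_frequency(fx_optics)] == 0))
  # radial symmetry up to grid anisotropy
  expect_equal(otf[dc[1] + 9, dc[2]], otf[dc[1], dc[2] + 9], tolerance = 1e-12)
  # undersampled optics are rejected
  expect_error(optics_model(na = 1.6, wavelength_em = 500, pixel_size = 90),
               "Nyquist")
})

test_that("raw rendering follows the modulated-blur-noise model", {
  pat0 <- pattern_set(2, modulation = 0, amplitude = 2)
  sc <- scene_constant(c(32, 32), 50)
  img <- render_raw(sc, pat0, fx_optics)
  expect_equal(max(img) - min(img), 0, tolerance = 1e-9)
  expect_equal(mean(img), 50, tolerance = 1e-9)  # I0/2 * scene with I0 = 2

  # Fourier peaks at +/- k_theta for a modulated noiseless render of a
  # uniform scene (spectrum: DC and the two fringe peaks only)
  set.seed(4)
  scu <- scene_constant(c(64, 64), 50)
  pat <- pattern_set(2, period = 4, modulation = 0.9, amplitude = 2)
  imgu <- render_raw(scu, pat, fx_optics, angle = 1, phase = 1)
  sp <- Mod(parsim:::fft2(imgu))
  fg <- parsim:::freq_grids(64, 64)
  k <- pat$k_vectors[1, ]
  near_p <- (fg$fy - k[1])^2 + (fg$fx - k[2])^2 < (2 / 64)^2
  near_m <- (fg$fy + k[1])^2 + (fg$fx + k[2])^2 < (2 / 64)^2
  elsewhere <- parsim:::freq_radius(64, 64) > 3 / 64 & !near_p & !near_m
  expect_gt(max(sp[near_p]), max(sp[elsewhere]))
  expect_gt(max(sp[near_m]), max(sp[elsewhere]))
  sc2 <- scene_beads(c(64, 64), 50, margin = 8)
  img2 <- render_raw(sc2, pat, fx_optics, angle = 1, phase = 1)

  # cosine phases cancel: sum over 0, 2pi/3, 4pi/3 equals 3x the m = 0 render
  imgs <- lapply(1:3, function(p) render_raw(sc2, pat, fx_optics, angle = 1, phase = p))
  flat <- render_raw(sc2, pattern_set(2, period = 4, modulation = 0, amplitude = 2),
                     fx_optics)
  expect_equal(Reduce(`+`, imgs), 3 * flat, tolerance = 1e-9)

  # photon conservation: blur preserves the pattern-weighted scene total
  illum <- parsim:::illumination_field(pat, dim(sc2), 1, 1)
  expect_equal(sum(img2), sum(unclass(sc2) * illum), tolerance = 1e-6)

  # invalid modulation rejected
  expect_error(pattern_set(2, modulation = 1.4))
  # determinism given a seeded noise model
  nm <- noise_model(seed = 77)
  expect_identical(render_raw(sc2, pat, fx_optics, noise = nm),
                   render_raw(sc2, pat, fx_optics, noise = nm))
})

test_that("frame assembly and cropping invert each other at zero jitter", {
  lay <- frame_layout(c(24, 32), margin = 4, jitter_sigma = 0)
  subs <- lapply(1:6, function(i) matrix(i + stats::runif(24 * 32), 24, 32))
  asm <- assemble_frame(subs, lay, noise_model(baseline_offset = 7))
  expect_equal(asm$shifts, matrix(0, 6, 2, dimnames = list(NULL, c("dy", "dx"))))
  st <- crop_subrois(asm$frame, lay)
  for (i in 1:6) expect_identical(st$images[[i]], subs[[i]])
  # background between rectangles is the camera baseline
  expect_equal(asm$frame[1, 1], 7)
  # scan order: pattern 1 occupies the grid row nearer the sensor center
  r <- lay$rects[lay$scan_order[1], ]
  expect_identical(unname(r["y0"]), 24 + 2 * 4)
  # mismatched sub-image shapes rejected
  expect_error(assemble_frame(c(subs[1:5], list(matrix(0, 10, 10))), lay),
               "shape")
})

test_that("jittered assembly records recoverable ground-truth shifts", {
  set.seed(12)
  sim <- simulate_sim_stack(seed = 31, snr_db = 4, n_angles = 2,
                            shape = c(48, 64), n_beads = 100)
  lay <- frame_layout(c(48, 64), jitter_sigma = 0.5)
  set.seed(5)
  asm <- assemble_frame(sim$images, lay, sim$noise)
  expect_false(all(asm$shifts == 0))
  stk <- crop_subrois(asm$frame, lay)
  reg <- suppressWarnings(register_subrois(stk))
  expd <- sweep(asm$shifts, 2, asm$shifts[1, ])
  expect_lt(sqrt(mean((reg$shifts - expd)^2)), 0.15)
})

test_that("simulated datasets are complete, counted and byte-reproducible", {
  dir <- withr::local_tempdir()
  cfg2 <- sim_config(n_angles = 2, n_timepoints = 2, shape = c(32, 48),
                     seed = 7, snr_db = 2, output = "subrois",
                     phase_jitter_sd = 0.3)
  r1 <- simulate_dataset(cfg2, dir, "two")
  expect_equal(r1$meta$n_subimages_per_timepoint, 6L)
  dd <- read_dataset(r1$tiff, r1$json)
  expect_length(dd$pages, 12)

  cfg3 <- sim_config(n_angles = 3, n_timepoints = 1, shape = c(32, 48),
                     seed = 7, snr_db = 2)
  r3 <- simulate_dataset(cfg3, dir, "three")
  expect_length(read_dataset(r3$tiff, r3$json)$pages, 9)

  # byte determinism
  r1b <- simulate_dataset(cfg2, dir, "two_again")
  expect_identical(readBin(r1$tiff, "raw", file.size(r1$tiff)),
                   readBin(r1b$tiff, "raw", file.size(r1b$tiff)))
  expect_identical(jsonlite::read_json(r1$json)[-1],
                   jsonlite::read_json(r1b$json)[-1])

  # vacuous dataset: empty stack, valid metadata
  r0 <- simulate_dataset(sim_config(n_timepoints = 0, seed = 1), dir, "empty")
  d0 <- read_dataset(r0$tiff, r0$json)
  expect_length(d0$pages, 0)
  expect_true(d0$meta$empty)

})

test_that("the spectral ground truth of noiseless renders matches the analytic components", {
  sim <- fx_stack_noiseless
  tr <- sim$truth
  for (a in 1:2) {
    truth_pat <- pattern_set(2, angles = tr$angles, period = tr$period,
                             phases = tr$phases, modulation = tr$modulation,
                             amplitude = tr$amplitude)
    d <- lapply(sim$images[(3 * a - 2):(3 * a)], parsim:::fft2)
    comps <- separate_orders(d, tr$phases[a, ], m = tr$modulation,
                             i0 = tr$amplitude)
    fc <- forward_components(sim$scene, sim$optics, tr$k_vectors[a, ])
    expect_lt(rel_frob(comps$order0, fc$order0), 1e-8)
    expect_lt(rel_frob(comps$minus, fc$minus), 1e-8)
    expect_lt(rel_frob(comps$plus, fc$plus), 1e-8)
  }
})
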