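# Illumination-parameter estimation: difference spectra, mixing-matrix
# separation, phase-difference optimization, prior-constrained k search,
# sub-pixel refinement.

test_that("difference spectra cancel the zero order and background exactly", {
  sim <- fx_stack_noiseless
  d <- lapply(sim$images[1:3], parsim:::fft2)
  diffs <- difference_spectra(d)
  # correlation of the differences with the true zero-order component ~ 0
  fc <- forward_components(sim$scene, sim$optics, sim$truth$k_vectors[1, ])
  corr <- function(a, b) Mod(sum(a * Conj(b))) /
    sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  expect_lt(corr(diffs$d21, fc$order0), 0.05)
  # identical inputs -> zero spectra
  z <- difference_spectra(list(d[[1]], d[[1]], d[[1]]))
  expect_equal(max(Mod(z$d21)), 0)
  # constant background adds only a DC term, which the difference removes
  db <- lapply(sim$images[1:3], function(x) parsim:::fft2(x + 100))
  diffs_b <- difference_spectra(db)
  expect_equal(diffs_b$d21, diffs$d21, tolerance = 1e-9)
  expect_error(difference_spectra(list(d[[1]], d[[2]], matrix(0i, 2, 2))),
               "shape")
})

test_that("order separation inverts the mixing matrix exactly", {
  # closed-form inverse for the symmetric 2pi/3 stepping at m = 1:
  # rows 1/3, (2/3) e^{-i phi_j}, (2/3) e^{+i phi_j}
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  sm <- separation_matrix(phases, 1)
  inv_closed <- rbind(rep(1 / 3, 3), 2 / 3 * exp(-1i * phases),
                      2 / 3 * exp(1i * phases))
  expect_equal(sm$inverse, inv_closed, tolerance = 1e-12, ignore_attr = TRUE)
  # degenerate matrices rejected
  expect_error(separation_matrix(c(0, 0, 2), 1), "singular|condition")
  expect_error(separate_orders(list(matrix(0i, 4, 4), matrix(0i, 4, 4),
                                    matrix(0i, 4, 4)), c(0, 1, 2), m = 0),
               "singular|condition")
})

test_that("phase differences, k, phase and modulation are recovered from noiseless stacks", {
  sim <- fx_stack_noiseless
  tr <- sim$truth
  for (a in 1:2) {
    il <- suppressWarnings(
      estimate_illumination(sim$images[(3 * a - 2):(3 * a)], sim$optics,
                            sim$pattern_nominal$angles[a]))
    true_diffs <- (tr$phases[a, 2:3] - tr$phases[a, 1]) %% (2 * pi)
    expect_lt(max(abs(wrap_rad(il$phase$phi - true_diffs))), 0.12)
    k_true <- tr$k_vectors[a, ]
    expect_lt(sqrt(sum((il$estimate$k - k_true)^2)) * fx_width, 0.05)
    expect_true(il$estimate$subpixel)
    # modulation within 1%; phases to the scene-overlap floor (see the
    # methods vignette on the finite-support limit of phase readout)
    expect_lt(abs(il$estimate$modulation - tr$modulation), 0.01)
    expect_lt(abs(wrap_rad(il$estimate$global_phase - tr$phases[a, 1])), 0.1)
  }
})

test_that("phase estimation degrades gracefully but stays useful at +4 dB", {
  errs <- c()
  for (seed in 1:3) {
    sim <- simulate_sim_stack(seed = seed + 700, snr_db = 4, n_angles = 2,
                              shape = c(192, 192))
    il <- suppressWarnings(
      estimate_illumination(sim$images[1:3], sim$optics,
                            sim$pattern_nominal$angles[1]))
    td <- (sim$truth$phases[1, 2:3] - sim$truth$phases[1, 1]) %% (2 * pi)
    errs <- c(errs, abs(wrap_rad(il$phase$phi - td)))
  }
  expect_lt(stats::median(errs), 0.06)
})

test_that("degenerate triplets raise explicit estimation failures", {
  sim <- fx_stack_noiseless
  w <- build_weight(sim$optics, c(192, 192))
  # equal phases: phases 2 and 3 identical to 1
  d_eq <- lapply(sim$images[c(1, 1, 1)], parsim:::fft2)
  expect_error(estimate_phase_differences(d_eq, w), "no modulation|degenerate")
  # unmodulated data
  flat <- render_raw(scene_constant(c(192, 192), 50),
                     pattern_set(2, modulation = 0), sim$optics)
  d_flat <- list(parsim:::fft2(flat), parsim:::fft2(flat + 1e-9),
                 parsim:::fft2(flat - 1e-9))
  expect_error(estimate_phase_differences(d_flat, w),
               "no modulation|degenerate")
})

test_that("the coarse search honors the ring mask and the angular prior", {
  sim <- fx_stack_noiseless
  tr <- sim$truth
  d <- lapply(sim$images[1:3], parsim:::fft2)
  true_diffs <- (tr$phases[1, 2:3] - tr$phases[1, 1]) %% (2 * pi)
  sepd <- parsim:::separate_differences(difference_spectra(d), true_diffs)
  # prior 2 degrees off the truth: found at the true pixel
  co <- coarse_k_search(sepd$A, sim$optics, tr$angles[1] + 2)
  k_true <- tr$k_vectors[1, ]
  expect_lt(sqrt(sum((co$k - k_true)^2)) * fx_width, 0.75)
  expect_identical(co$precision, "pixel")

  # prior off by 10 degrees with a 2.5 degree sector: true peak excluded
  off <- suppressWarnings(coarse_k_search(sepd$A, sim$optics,
                                          tr$angles[1] + 10))
  expect_true(off$on_boundary ||
                sqrt(sum((off$k - k_true)^2)) * fx_width > 2)

  # a strong DC residual is excluded by the 0.5 k_c lower ring bound
  spiked <- sepd$A
  spiked[1, 1] <- 1e9
  co2 <- coarse_k_search(spiked, sim$optics, tr$angles[1] + 2)
  expect_gt(co2$magnitude, 0.5 * cutoff_frequency(sim$optics))

  # misconfigured mask errors
  expect_error(coarse_k_search(sepd$A, sim$optics, 35, ring = c(2.2, 2.3)),
               "empty")
})

test_that("the angular prior shrinks the search domain by the sector fraction", {
  sim <- fx_stack_noiseless
  d <- lapply(sim$images[1:3], parsim:::fft2)
  sepd <- parsim:::separate_differences(difference_spectra(d), c(2.09, 4.19))
  co <- coarse_k_search(sepd$A, sim$optics, sim$truth$angles[1])
  kc <- cutoff_frequency(sim$optics)
  kr <- parsim:::freq_radius(192, 192)
  ring_n <- sum(kr >= 0.5 * kc & kr <= 1.1 * kc)
  # 5 degrees of 360 with some discretization slack
  expect_lt(co$n_search, ring_n / (360 / 5) * 1.6)
  expect_gt(co$n_search, 0)
})

test_that("the default weight suppresses DC and is minimized near the true step", {
  w <- build_weight(fx_optics, c(192, 192))
  expect_equal(w[1, 1], 0)
  expect_true(all(w >= 0))
  sim <- fx_stack_noiseless
  d <- lapply(sim$images[1:3], parsim:::fft2)
  ph <- estimate_phase_differences(d, w, refine = FALSE)
  td <- (sim$truth$phases[1, 2:3] - sim$truth$phases[1, 1]) %% (2 * pi)
  # grid optimum lands within the grid resolution of the truth
  res2 <- diff(ph$trace$phi2[1:2]); res3 <- diff(ph$trace$phi3[1:2])
  expect_lt(abs(wrap_rad(ph$phi[1] - td[1])), 3 * res2 + 0.15)
  expect_lt(abs(wrap_rad(ph$phi[2] - td[2])), 3 * res3 + 0.15)
})
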