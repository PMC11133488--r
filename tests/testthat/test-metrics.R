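# Quantification: SNR formulas, FWHM measurement, track statistics.

test_that("SNR follows the mean/variance formulas exactly", {
  # noise region mean 10 variance 4, signal region mean 100:
  # Signal = 90, SNR = 10 log10(90/4) = 13.52 dB
  img <- matrix(0, 8, 8)
  img[, 1:4] <- rep(c(8, 12), 16)       # mean 10, population variance 4
  img[, 5:8] <- 100
  noise_r <- col(img) <= 4
  signal_r <- col(img) >= 5
  rep <- estimate_snr(img, noise_r, signal_r)
  expect_equal(rep$mu_noise, 10)
  expect_equal(rep$mse_noise, 4)
  expect_equal(rep$signal, 90)
  expect_equal(rep$snr_db, 10 * log10(22.5))
  expect_equal(round(rep$snr_db, 2), 13.52)

  img2 <- img; img2[, 1:4] <- 10
  expect_error(estimate_snr(img2, noise_r, signal_r), "constant noise")
  # non-positive signal reported as failure, not an error
  img3 <- img; img3[, 5:8] <- 5
  r3 <- estimate_snr(img3, noise_r, signal_r)
  expect_true(r3$failed)
  expect_true(is.na(r3$snr_db))
  expect_error(estimate_snr(img, noise_r, noise_r), "overlap")
})

test_that("SNR matches a naive two-pass oracle on randomized integer images", {
  set.seed(99)
  for (rep_i in 1:25) {
    nr <- sample(6:14, 1); nc <- sample(6:14, 1)
    img <- matrix(sample.int(50, nr * nc, replace = TRUE), nr, nc)
    nmask <- matrix(FALSE, nr, nc); nmask[, 1:3] <- TRUE
    smask <- matrix(FALSE, nr, nc); smask[, (nc - 1):nc] <- TRUE
    # naive two-pass oracle, written independently of the implementation
    nv <- c(); for (i in 1:nr) for (j in 1:3) nv <- c(nv, img[i, j])
    mu_n <- sum(nv) / length(nv)
    mse <- 0; for (v in nv) mse <- mse + (v - mu_n)^2
    mse <- mse / length(nv)
    sv <- c(); for (i in 1:nr) for (j in (nc - 1):nc) sv <- c(sv, img[i, j])
    mu_s <- sum(sv) / length(sv)
    if (mse == 0) { expect_error(estimate_snr(img, nmask, smask)); next }
    got <- estimate_snr(img, nmask, smask)
    expect_equal(got$mu_noise, mu_n, tolerance = 1e-12)
    expect_equal(got$mse_noise, mse, tolerance = 1e-12)
    expect_equal(got$mu_signal, mu_s, tolerance = 1e-12)
    if (mu_s - mu_n > 0)
      expect_equal(got$snr_db, 10 * log10((mu_s - mu_n) / mse), tolerance = 1e-12)
  }
})

test_that("stack SNR averages per-image quantities and tracks failures", {
  img <- matrix(0, 8, 8); img[, 1:4] <- rep(c(8, 12), 16); img[, 5:8] <- 100
  noise_r <- col(img) <= 4; signal_r <- col(img) >= 5
  st <- stack_snr(list(img, img, img), noise_r, signal_r)
  single <- estimate_snr(img, noise_r, signal_r)
  expect_equal(st$snr_db, single$snr_db)
  expect_equal(st$signal, single$signal)
  # arithmetic mean of per-image SNRs: 0 dB and 6.02 dB -> 3.01 dB
  imgA <- img; imgA[, 5:8] <- 10 + 4          # Signal 4,  SNR 0 dB
  imgB <- img; imgB[, 5:8] <- 10 + 4 * 10^0.602  # SNR 6.02 dB
  st2 <- stack_snr(list(imgA, imgB), noise_r, signal_r)
  expect_equal(st2$snr_db, (0 + 6.02) / 2, tolerance = 1e-3)
  # failing image excluded and counted
  bad <- img; bad[, 5:8] <- 0
  st3 <- stack_snr(list(img, bad), noise_r, signal_r)
  expect_equal(st3$n_failed, 1L)
  expect_equal(st3$failed_idx, 2L)
})

test_that("simulated stacks hit their configured SNR target", {
  snrs <- vapply(1:6, function(s) {
    sim <- simulate_sim_stack(seed = 500 + s, snr_db = -2, n_angles = 2,
                              shape = c(96, 96))
    stack_snr(sim$images, sim$noise_region, sim$signal_region)$snr_db
  }, numeric(1))
  expect_lt(abs(mean(snrs) - (-2)), 0.5)
})

test_that("FWHM measurement is unbiased on Gaussian spots", {
  for (sigma in c(1, 2, 4)) {
    g <- outer(exp(-((1:41) - 21)^2 / (2 * sigma^2)),
               exp(-((1:41) - 21)^2 / (2 * sigma^2))) * 50 + 5
    fw <- measure_fwhm(g, c(21, 21), pixel_size = 65)
    expect_true(fw$converged)
    expect_equal(fw$fwhm_nm, 2 * sqrt(2 * log(2)) * sigma * 65,
                 tolerance = 0.01)
  }
  # sigma = 2 px at 65 nm/px: the 2.3548 sigma identity, ~306 nm
  g2 <- outer(exp(-((1:41) - 21)^2 / 8), exp(-((1:41) - 21)^2 / 8))
  expect_equal(measure_fwhm(g2, c(21, 21), 65)$fwhm_nm, 306.2, tolerance = 0.01)
  # flat image: reported fit failure
  expect_false(measure_fwhm(matrix(3, 41, 41), c(21, 21), 65)$converged)
})

test_that("track statistics project, label and downsample correctly", {
  # uniform motion at 1 um/s sampled every 7.35 ms along x
  px <- 65
  n <- 101
  t_ms <- (0:(n - 1)) * 7.35
  x_um <- t_ms / 1000 * 1  # 1 um/s
  tr <- data.frame(t_ms = t_ms, y_px = 0, x_px = x_um * 1000 / px)
  ts <- track_stats(tr, pixel_size = px, step = 25)
  expect_equal(unname(ts$velocity), rep(1, n - 1), tolerance = 1e-9)
  expect_equal(unname(ts$downsampled$velocity),
               rep(1, length(ts$downsampled$velocity)), tolerance = 1e-9)
  expect_true(all(ts$direction == "forward" | abs(ts$displacement_px) < 0.5))

  # V' at step 1 equals V exactly
  ts1 <- track_stats(tr, pixel_size = px, step = 1)
  expect_identical(ts1$velocity, ts1$downsampled$velocity)

  # saltatory track: bursts at 20 um/s and pauses; coarse sampling
  # flattens the peak velocity (mean-value bound)
  set.seed(1)
  dt <- 7.35
  v_inst <- rep(c(20, 0, 0, 0, 0), length.out = 400)  # um/s, bursty
  x <- cumsum(v_inst * dt / 1000) * 1000 / px
  tr2 <- data.frame(t_ms = (1:400) * dt, y_px = 0, x_px = x)
  ts2 <- track_stats(tr2, pixel_size = px, step = 25)
  expect_true(max(abs(ts2$downsampled$velocity)) <= max(abs(ts2$velocity)) + 1e-9)
  expect_lt(max(abs(ts2$downsampled$velocity)), 0.3 * max(abs(ts2$velocity)))
  # static dead-band labels the pauses
  expect_true(any(ts2$direction == "static"))
  expect_error(track_stats(tr2[1, ], pixel_size = px), "2 points")
})
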