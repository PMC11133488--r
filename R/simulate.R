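# Forward model: renders raw SIM sub-images of known synthetic scenes and
# assembles full parallel-acquisition frames, so every downstream stage can
# be tested against ground truth.

#' Synthetic scene of point emitters ("beads")
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param n_beads number of emitters.
#' @param amplitude photons per emitter per unit exposure.
#' @param margin emitters are kept at least this many pixels from every
#'   edge (leaves clean background for noise-region statistics).
#' @param min_distance optional minimum emitter spacing in pixels
#'   (rejection sampling; for resolution fixtures needing isolated beads).
#' @param pixel_size nm/pixel (metadata only).
#' @return non-negative matrix of class `scene` with an `emitters`
#'   attribute (data frame of y, x, amplitude; 0-based sub-pixel centers).
#' @export
scene_beads <- function(shape = c(128, 128), n_beads = 60, amplitude = 100,
                        margin = 16, min_distance = 0, pixel_size = 65) {
  stopifnot(all(shape >= 2 * margin + 4), n_beads >= 0)
  s <- matrix(0, shape[1], shape[2])
  em <- data.frame(y = numeric(0), x = numeric(0), amplitude = numeric(0))
  if (n_beads > 0) {
    if (min_distance > 0) {
      y <- x <- numeric(0)
      tries <- 0L
      while (length(y) < n_beads && tries < 200L * n_beads) {
        tries <- tries + 1L
        yy <- stats::runif(1, margin, shape[1] - 1 - margin)
        xx <- stats::runif(1, margin, shape[2] - 1 - margin)
        if (!length(y) || min((y - yy)^2 + (x - xx)^2) >= min_distance^2) {
          y <- c(y, yy); x <- c(x, xx)
        }
      }
      if (length(y) < n_beads)
        warning("placed only ", length(y), " of ", n_beads,
                " beads at min_distance ", min_distance)
    } else {
      y <- stats::runif(n_beads, margin, shape[1] - 1 - margin)
      x <- stats::runif(n_beads, margin, shape[2] - 1 - margin)
    }
    n_beads <- length(y)
    em <- data.frame(y = y, x = x, amplitude = amplitude)
    # nearest-pixel deposition; sub-pixel truth kept in the emitter list
    for (i in seq_len(n_beads)) {
      r <- round(y[i]) + 1; c <- round(x[i]) + 1
      s[r, c] <- s[r, c] + amplitude
    }
  }
  structure(s, emitters = em, pixel_size = pixel_size, class = c("scene", "matrix"))
}

#' Spatially constant scene
#' @param shape `c(rows, cols)`.
#' @param value photons per pixel per unit exposure.
#' @param pixel_size nm/pixel.
#' @export
scene_constant <- function(shape = c(64, 64), value = 50, pixel_size = 65) {
  stopifnot(value >= 0)
  structure(matrix(value, shape[1], shape[2]), pixel_size = pixel_size,
            class = c("scene", "matrix"))
}

#' Camera noise model
#'
#' Standard sCMOS approximation: Poisson shot noise on the expected photon
#' image, a conversion gain, additive Gaussian read noise and a constant
#' baseline offset.
#'
#' @param photon_scale conversion gain, counts/photon.
#' @param read_noise_sigma read noise sd, counts.
#' @param baseline_offset constant camera baseline, counts.
#' @param seed optional integer; when set, rendering with this model is
#'   reproducible on its own.
#' @export
noise_model <- function(photon_scale = 1, read_noise_sigma = 8,
                        baseline_offset = 100, seed = NULL) {
  stopifnot(photon_scale > 0, read_noise_sigma >= 0, baseline_offset >= 0)
  structure(list(photon_scale = photon_scale,
                 read_noise_sigma = read_noise_sigma,
                 baseline_offset = baseline_offset, seed = seed),
            class = "noise_model")
}

#' Render one raw SIM sub-image
#'
#' Multiplies the scene by the sinusoidal illumination of one
#' (angle, phase), blurs with the diffraction OTF, scales by the exposure
#' and (optionally) applies the camera noise model:
#' `Poisson(blur(scene * I0/2 * (1 + m cos(2 pi k.r + phi))) * exposure) *
#' gain + N(0, sigma_read) + offset`.
#'
#' @param scene a [scene_beads()]/[scene_constant()] matrix (photons).
#' @param pattern a [pattern_set()].
#' @param optics an [optics_model()].
#' @param noise a [noise_model()] or `NULL` for the noiseless expectation
#'   (no gain/offset applied).
#' @param exposure_scale dimensionless exposure multiplier.
#' @param angle,phase indices into the pattern set.
#' @return raw image matrix (counts).
#' @export
render_raw <- function(scene, pattern, optics, noise = NULL,
                       exposure_scale = 1, angle = 1L, phase = 1L) {
  stopifnot(inherits(pattern, "pattern_set"), inherits(optics, "optics_model"),
            exposure_scale > 0,
            angle >= 1, angle <= pattern$n_angles, phase %in% 1:3)
  illum <- illumination_field(pattern, dim(scene), angle, phase)
  h <- otf_matrix(optics, dim(scene))
  expected <- Re(ifft2(fft2(unclass(scene) * illum) * h)) * exposure_scale
  if (is.null(noise)) return(expected)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  counts <- stats::rpois(length(expected), pmax(expected, 0)) * noise$photon_scale
  counts <- counts + stats::rnorm(length(expected), 0, noise$read_noise_sigma) +
    noise$baseline_offset
  matrix(counts, nrow(expected), ncol(expected))
}

#' Sub-ROI frame layout
#'
#' Geometry of the 2 x 3 grid of sub-ROI rectangles inside one opened
#' sensor frame, plus the scan order of the sensor half and the rigid
#' jitter emulating galvo vibration. Rectangles are 0-based, half-open
#' `[y0, y1) x [x0, x1)` pixel intervals.
#'
#' @param subroi_shape `c(rows, cols)` of one sub-ROI.
#' @param margin pixels between rectangles and to the frame edge.
#' @param sensor_half `"top"` or `"bottom"` (fixes the scan order).
#' @param jitter_sigma sd (pixels) of the per-sub-ROI rigid shift.
#' @return object of class `frame_layout` with elements `rects` (6 x 4
#'   matrix `y0, x0, y1, x1` in scan order slots 1..6 = grid row-major),
#'   `frame_shape`, `scan_order`, `margin`, `jitter_sigma`.
#' @export
frame_layout <- function(subroi_shape = c(48, 64), margin = 6,
                         sensor_half = "top", jitter_sigma = 0) {
  stopifnot(all(subroi_shape >= 16), margin >= 0, jitter_sigma >= 0)
  sr <- subroi_shape[1]; sc <- subroi_shape[2]
  frame_shape <- c(2 * sr + 3 * margin, 3 * sc + 4 * margin)
  rects <- matrix(NA_real_, 6, 4,
                  dimnames = list(NULL, c("y0", "x0", "y1", "x1")))
  for (g in 1:2) for (cc in 1:3) {
    i <- (g - 1) * 3 + cc
    y0 <- margin + (g - 1) * (sr + margin)
    x0 <- margin + (cc - 1) * (sc + margin)
    rects[i, ] <- c(y0, x0, y0 + sr, x0 + sc)
  }
  structure(list(rects = rects, frame_shape = frame_shape,
                 scan_order = scan_order(sensor_half), margin = margin,
                 jitter_sigma = jitter_sigma, sensor_half = sensor_half),
            class = "frame_layout")
}

#' Assemble six sub-images into one full sensor frame
#'
#' Places the sub-images (in pattern order P1..P6) at their scan-order grid
#' rectangles, applying an independent rigid shift per sub-ROI drawn from
#' `N(0, jitter_sigma)` (integer part moves the rectangle, fractional part
#' translates the content). Background pixels are set to the camera
#' baseline offset.
#'
#' @param sub_images list of 6 equal-shape matrices in pattern order.
#' @param layout a [frame_layout()].
#' @param noise a [noise_model()] (supplies the background offset) or `NULL`.
#' @return list with `frame` and `shifts` (6 x 2 matrix `dy, dx`, the
#'   ground-truth applied shifts in pattern order).
#' @export
assemble_frame <- function(sub_images, layout, noise = NULL) {
  stopifnot(length(sub_images) == 6, inherits(layout, "frame_layout"))
  shp <- vapply(sub_images, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("sub-images must share one shape")
  r1 <- layout$rects[1, ]
  if (shp[1, 1] != r1["y1"] - r1["y0"] || shp[2, 1] != r1["x1"] - r1["x0"])
    stop("sub-image shape does not match the layout rectangles")
  offset <- if (is.null(noise)) 0 else noise$baseline_offset
  frame <- matrix(offset, layout$frame_shape[1], layout$frame_shape[2])
  shifts <- matrix(0, 6, 2, dimnames = list(NULL, c("dy", "dx")))
  rects <- matrix(NA_real_, 6, 4)  # jittered rectangles, pattern order
  for (p in 1:6) {
    s <- if (layout$jitter_sigma > 0) stats::rnorm(2, 0, layout$jitter_sigma) else c(0, 0)
    shifts[p, ] <- s
    pos <- layout$scan_order[p]
    rects[p, ] <- layout$rects[pos, ] + round(s)[c(1, 2, 1, 2)]
  }
  fs <- layout$frame_shape
  for (p in 1:6) {
    if (rects[p, 1] < 0 || rects[p, 2] < 0 || rects[p, 3] > fs[1] || rects[p, 4] > fs[2])
      stop("sub-ROI for pattern ", p, " falls outside the frame after jitter")
    for (q in seq_len(p - 1)) {
      if (rects[p, 1] < rects[q, 3] && rects[q, 1] < rects[p, 3] &&
          rects[p, 2] < rects[q, 4] && rects[q, 2] < rects[p, 4])
        stop("sub-ROIs for patterns ", q, " and ", p, " overlap after jitter")
    }
    img <- sub_images[[p]]
    frac <- shifts[p, ] - round(shifts[p, ])
    if (any(frac != 0)) img <- fourier_translate(img, frac)
    frame[(rects[p, 1] + 1):rects[p, 3], (rects[p, 2] + 1):rects[p, 4]] <- img
  }
  list(frame = frame, shifts = shifts)
}

#' Simulation configuration
#'
#' Collects everything [simulate_dataset()] needs. All randomness is driven
#' by `seed`.
#'
#' @param n_angles 2 or 3; with 3 angles the dataset is written as
#'   per-pattern sub-image stacks (9 per time point), with 2 angles as full
#'   2 x 3 frames (6 sub-ROIs per time point).
#' @param n_timepoints time points to simulate.
#' @param shape sub-ROI shape `c(rows, cols)`.
#' @param optics,pattern,noise component models (defaults built if `NULL`).
#' @param layout a [frame_layout()] for frame output (2 angles only).
#' @param scene a scene matrix; default fresh bead scene.
#' @param snr_db target raw-frame SNR (dB, Methods definition); the pattern
#'   amplitude is set in closed form to meet it (`NA` = leave amplitude).
#' @param phase_jitter_sd sd (radians) of the per-image illumination-phase
#'   deviation from the nominal `2pi/3` steps (galvo vibration surrogate).
#' @param output `"frames"` or `"subrois"`.
#' @param seed integer RNG seed.
#' @export
sim_config <- function(n_angles = 2L, n_timepoints = 1L, shape = c(48, 64),
                       optics = NULL, pattern = NULL, noise = NULL,
                       layout = NULL, scene = NULL, snr_db = NA,
                       phase_jitter_sd = 0, output = NULL, seed = 1L) {
  n_angles <- as.integer(n_angles)
  stopifnot(n_angles %in% c(2L, 3L), n_timepoints >= 0)
  if (is.null(optics)) optics <- optics_model()
  if (is.null(pattern)) pattern <- pattern_set(n_angles)
  if (is.null(noise)) noise <- noise_model()
  if (is.null(output)) output <- if (n_angles == 2L) "frames" else "subrois"
  if (output == "frames" && n_angles != 2L)
    stop("full-frame output assembles a 2 x 3 grid and needs 2 angles")
  if (is.null(layout) && output == "frames") layout <- frame_layout(shape)
  list(n_angles = n_angles, n_timepoints = as.integer(n_timepoints),
       shape = shape, optics = optics, pattern = pattern, noise = noise,
       layout = layout, scene = scene, snr_db = snr_db,
       phase_jitter_sd = phase_jitter_sd, output = output,
       seed = as.integer(seed))
}

# Closed-form amplitude for a target SNR (dB) under the Methods definition
# SNR = 10 log10((mu_signal - mu_noise) / MSE_noise): the noise region
# carries only read noise (variance sigma^2), so the required mean signal is
# sigma^2 * 10^(snr/10) counts above baseline.
amplitude_for_snr <- function(scene, optics, pattern, noise, snr_db) {
  wf <- Re(ifft2(fft2(unclass(scene)) * otf_matrix(optics, dim(scene)))) / 2
  region <- wf > 0.5 * max(wf)
  target <- noise$read_noise_sigma^2 * 10^(snr_db / 10)
  target / mean(wf[region]) / noise$photon_scale
}

# Pixels used as the pure-noise region of a simulated sub-image: the top
# margin strip (scenes keep emitters away from the edges).
noise_region_mask <- function(shape, depth = 8) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[seq_len(depth), ] <- TRUE
  m
}

# Signal region: pixels whose noiseless widefield exceeds half its maximum.
signal_region_mask <- function(scene, optics) {
  wf <- Re(ifft2(fft2(unclass(scene)) * otf_matrix(optics, dim(scene))))
  wf > 0.5 * max(wf)
}

#' Simulate a registered low-SNR raw pattern stack with ground truth
#'
#' The study-conditions generator used throughout the tests: a bead scene
#' under a full `n_angles x 3` pattern set with per-acquisition deviations
#' from the nominal illumination (small angle and period errors, per-image
#' phase jitter emulating galvo vibration) and camera noise calibrated to a
#' target SNR under the Methods definition.
#'
#' @param seed integer seed (drives scene, truth deviations and noise).
#' @param snr_db target SNR in dB; `NA` for noiseless expectations.
#' @param n_angles 2 or 3.
#' @param shape image shape.
#' @param optics an [optics_model()].
#' @param period nominal fringe period (pixels).
#' @param modulation true modulation depth.
#' @param phase_jitter_sd sd (rad) of per-image phase deviation from the
#'   nominal steps (phases 2 and 3; phase 1 anchors the global phase).
#' @param angle_jitter_sd sd (deg) of the true angle around nominal.
#' @param n_beads emitters in the scene; default a dense field of 0.05
#'   emitters per pixel^2 (confluent punctate labeling, the regime where
#'   spectral parameter estimation has realistic support).
#' @param noise a [noise_model()] (ignored when `snr_db` is `NA`).
#' @return list: `images` (list in pattern order: angle-major, 3 phases
#'   each), `truth` (k-vectors, angles, period, phases, modulation,
#'   amplitude), `pattern_nominal`, `optics`, `scene`, `noise`, region masks.
#' @export
simulate_sim_stack <- function(seed = 1L, snr_db = -2, n_angles = 2L,
                               shape = c(128, 128), optics = optics_model(),
                               period = 3.9, modulation = 0.8,
                               phase_jitter_sd = 0.3, angle_jitter_sd = 0.5,
                               n_beads = NULL, noise = noise_model()) {
  set.seed(as.integer(seed))
  if (is.null(n_beads)) n_beads <- round(0.05 * prod(shape))
  scene <- scene_beads(shape, n_beads = n_beads, amplitude = 100,
                       pixel_size = optics$pixel_size)
  nominal <- pattern_set(n_angles, period = period, modulation = modulation)
  true_angles <- nominal$angles + stats::rnorm(n_angles, 0, angle_jitter_sd)
  true_period <- period * (1 + stats::rnorm(1, 0, 0.003))
  phases <- matrix(0, n_angles, 3)
  for (a in seq_len(n_angles)) {
    g <- stats::runif(1, 0, 2 * pi)
    phases[a, ] <- g + c(0, 2 * pi / 3, 4 * pi / 3) +
      c(0, stats::rnorm(2, 0, phase_jitter_sd))
  }
  amp <- if (is.na(snr_db)) 1 else
    amplitude_for_snr(scene, optics, nominal, noise, snr_db)
  truth_pat <- pattern_set(n_angles, angles = true_angles, period = true_period,
                           phases = phases, modulation = modulation,
                           amplitude = amp)
  nm <- if (is.na(snr_db)) NULL else noise
  images <- vector("list", 3L * n_angles)
  labels <- matrix(0L, 3L * n_angles, 2,
                   dimnames = list(NULL, c("angle", "phase")))
  i <- 0L
  for (a in seq_len(n_angles)) for (p in 1:3) {
    i <- i + 1L
    images[[i]] <- render_raw(scene, truth_pat, optics, noise = nm,
                              angle = a, phase = p)
    labels[i, ] <- c(a, p)
  }
  list(images = images, labels = labels,
       truth = list(k_vectors = truth_pat$k_vectors, angles = true_angles,
                    period = true_period, phases = phases,
                    modulation = modulation, amplitude = amp,
                    offset = if (is.na(snr_db)) 0 else noise$baseline_offset),
       pattern_nominal = nominal, optics = optics, scene = scene, noise = nm,
       noise_region = noise_region_mask(shape),
       signal_region = signal_region_mask(scene, optics))
}

#' Simulate a dataset to disk
#'
#' Writes a multi-page 16-bit TIFF stack (full frames or per-pattern
#' sub-images) plus a JSON sidecar with the complete ground truth (true
#' k-vectors, phases, modulation, applied shifts, seeds, intensity scale).
#' Re-running with the same config reproduces the files byte-for-byte.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @param basename file stem for `<stem>.tif` / `<stem>.json`.
#' @return invisibly, list with `tiff`, `json` paths and the metadata.
#' @export
simulate_dataset <- function(config, dir, basename = "parsim_sim") {
  stopifnot(is.list(config), !is.null(config$seed))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  shape <- config$shape
  scene <- config$scene
  if (is.null(scene))
    scene <- scene_beads(shape, n_beads = max(10, round(prod(shape) / 250)),
                         margin = min(16, min(shape) %/% 4),
                         pixel_size = config$optics$pixel_size)
  pattern <- config$pattern
  if (!is.na(config$snr_db))
    pattern$amplitude <- amplitude_for_snr(scene, config$optics, pattern,
                                           config$noise, config$snr_db)
  n_sub <- 3L * config$n_angles
  pages <- list()
  all_shifts <- list()
  all_phases <- list()
  for (t in seq_len(config$n_timepoints)) {
    ph <- pattern$phases
    if (config$phase_jitter_sd > 0)
      ph[, 2:3] <- ph[, 2:3] +
        matrix(stats::rnorm(2L * config$n_angles, 0, config$phase_jitter_sd),
               config$n_angles, 2)
    pat_t <- pattern; pat_t$phases <- ph
    subs <- vector("list", n_sub)
    i <- 0L
    for (a in seq_len(config$n_angles)) for (p in 1:3) {
      i <- i + 1L
      subs[[i]] <- render_raw(scene, pat_t, config$optics, noise = config$noise,
                              angle = a, phase = p)
    }
    all_phases[[t]] <- ph
    if (config$output == "frames") {
      asm <- assemble_frame(subs, config$layout, config$noise)
      pages[[t]] <- asm$frame
      all_shifts[[t]] <- asm$shifts
    } else {
      pages <- c(pages, subs)
      all_shifts[[t]] <- matrix(0, n_sub, 2)
    }
  }
  # 16-bit quantization scale chosen from the data range
  peak <- if (length(pages)) max(1, max(vapply(pages, max, numeric(1)))) else 1
  scale <- 65535 / (1.1 * peak)
  tif <- file.path(dir, paste0(basename, ".tif"))
  jsn <- file.path(dir, paste0(basename, ".json"))
  if (length(pages)) {
    tiff::writeTIFF(lapply(pages, function(p) pmax(pmin(p * scale, 65535), 0) / 65535),
                    tif, bits.per.sample = 16L)
  } else {
    # vacuous dataset: no pages; write an empty placeholder stack of one
    # zero page so the file exists, flagged in the metadata
    tiff::writeTIFF(list(matrix(0, 16, 16)), tif, bits.per.sample = 16L)
  }
  meta <- list(seed = config$seed, n_angles = config$n_angles,
               n_timepoints = config$n_timepoints,
               n_subimages_per_timepoint = n_sub,
               output = config$output, shape = shape,
               intensity_scale = scale,
               empty = config$n_timepoints == 0L,
               optics = unclass(config$optics),
               pattern = list(angles = pattern$angles, period = pattern$period,
                              k_vectors = pattern$k_vectors,
                              modulation = pattern$modulation,
                              amplitude = pattern$amplitude),
               phases = lapply(all_phases, function(m) unclass(m)),
               noise = unclass(config$noise),
               shifts = lapply(all_shifts, function(m) unclass(m)))
  jsonlite::write_json(meta, jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tiff = tif, json = jsn, meta = meta))
}

#' Read a simulated dataset back
#'
#' @param tif path to the TIFF stack written by [simulate_dataset()].
#' @param json path to its JSON sidecar.
#' @return list with `pages` (count-scaled matrices) and `meta`.
#' @export
read_dataset <- function(tif, json) {
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  pages <- lapply(pages, function(p) p * 65535 / meta$intensity_scale)
  if (isTRUE(meta$empty)) pages <- list()
  list(pages = pages, meta = meta)
}
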