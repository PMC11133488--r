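# Super-resolution assembly: order shifting on the upsampled grid,
# two-step spectral fusion (generalized Wiener combination + apodization to
# the extended cutoff), synthesized SIM OTF/PSF, final RL deconvolution,
# and rolling (sliding-window) reconstruction of time series.

#' Shift a spectral order by a k-vector
#'
#' Evaluates `G(k + k0)` through an exact spatial phase ramp
#' (`F[F^-1(G)(r) exp(-2i pi k0.r)]`); energy is conserved (Parseval).
#' Call on the upsampled grid so the shifted support stays representable.
#'
#' @param spectrum complex matrix, unshifted frequency layout.
#' @param k `c(ky, kx)` in cycles/pixel of the grid the spectrum lives on.
#' @return shifted spectrum.
#' @export
shift_order <- function(spectrum, k) {
  stopifnot(length(k) == 2, all(is.finite(k)))
  if (sqrt(sum(k^2)) >= 0.5)
    stop("|k| = ", signif(sqrt(sum(k^2)), 4),
         " cycles/pixel is beyond the representable range")
  shift_spectrum(spectrum, k)
}

#' Fusion filter parameters
#'
#' @param wiener generalized-Wiener regularization parameter.
#' @param notch_sigma sd of the Gaussian notch at the residual zero-order
#'   peaks, in frequency bins of the original (pre-upsampling) grid.
#' @param notch_depth notch depth in `[0, 1]` (1 = full suppression).
#' @param apodize logical: apply the triangular second-step apodization to
#'   the extended cutoff.
#' @export
fusion_filters <- function(wiener = 0.05, notch_sigma = 1.5,
                           notch_depth = 1.0, apodize = TRUE) {
  stopifnot(wiener >= 0, notch_sigma > 0, notch_depth >= 0, notch_depth <= 1)
  structure(list(wiener = wiener, notch_sigma = notch_sigma,
                 notch_depth = notch_depth, apodize = apodize),
            class = "fusion_filters")
}

#' Fuse shifted spectral components into the super-resolved spectrum
#'
#' Step 1: generalized Wiener combination
#' `sum(m_d conj(H_d) D_d) / (sum(m_d^2 H_d^2) + w^2)` over all components
#' `d`, each `H_d` the component's shifted OTF, with a Gaussian notch
#' suppressing the residual zero-order peak of every shifted side
#' component. Step 2: multiplication by a triangular apodization that
#' tapers to zero at the extended cutoff `k_c + max |k_theta|`. The same
#' combination applied to the OTFs yields the synthesized SIM OTF used as
#' the final deconvolution kernel's spectrum.
#'
#' @param components list of entries, each a list with `spectrum` (already
#'   shifted to its true position, unshifted frequency layout), `k_shift`
#'   (the shift applied, `c(ky, kx)` cycles/pixel of this grid; `c(0, 0)`
#'   for zero orders), and `m` (modulation weight; 1 for zero orders).
#' @param optics the [optics_model()] of the grid the components live on
#'   (for the upsampled grid, halve the pixel size).
#' @param filters a [fusion_filters()].
#' @return list: `fused` (complex spectrum), `synthesized_otf` (real,
#'   unshifted layout, 1 at DC), `extended_cutoff` (cycles/pixel).
#' @export
fuse_spectra <- function(components, optics, filters = fusion_filters()) {
  stopifnot(length(components) >= 1)
  shp <- dim(components[[1]]$spectrum)
  if (is.null(shp)) stop("components must carry matrix spectra")
  fg <- freq_grids(shp[1], shp[2])
  kc <- cutoff_frequency(optics)
  num <- matrix(0 + 0i, shp[1], shp[2])
  den <- matrix(0, shp[1], shp[2])
  onum <- matrix(0, shp[1], shp[2])
  kmax <- 0
  nbin <- filters$notch_sigma / max(shp)  # original-grid bins on this grid
  for (comp in components) {
    if (is.null(comp$spectrum) || is.null(comp$k_shift) || is.null(comp$m))
      stop("each component needs spectrum, k_shift and m")
    hd <- otf_matrix(optics, shp, k_off = comp$k_shift)
    d <- comp$spectrum
    if (any(comp$k_shift != 0)) {
      # residual zero-order leakage of a shifted side order peaks at -k_shift
      dist2 <- (fg$fy + comp$k_shift[1])^2 + (fg$fx + comp$k_shift[2])^2
      d <- d * (1 - filters$notch_depth * exp(-dist2 / (2 * (2 * nbin)^2)))
      kmax <- max(kmax, sqrt(sum(comp$k_shift^2)))
    }
    num <- num + comp$m * hd * d
    den <- den + comp$m^2 * hd^2
    onum <- onum + comp$m^2 * hd^2
  }
  fused <- num / (den + filters$wiener^2)
  otf <- onum / (onum + filters$wiener^2)
  k_ext <- kc + kmax
  if (filters$apodize) {
    kr <- sqrt(fg$fy^2 + fg$fx^2)
    w2 <- pmax(1 - kr / k_ext, 0)
    fused <- fused * w2
    otf <- otf * w2
  }
  otf <- otf / otf[1, 1]
  list(fused = fused, synthesized_otf = otf, extended_cutoff = k_ext)
}

#' Real-space kernel of the synthesized SIM OTF
#'
#' Inverse transform of the fused OTF, recentered, truncated to a compact
#' support and renormalized to sum 1. The kernel keeps its (signed)
#' sidelobe structure: the fused passband is no longer circular, so the
#' kernel is anisotropic along vs between the pattern angles.
#'
#' @param synthesized_otf real matrix (unshifted layout) from
#'   [fuse_spectra()].
#' @param support_radius half-size of the truncated kernel, pixels.
#' @return `(2 support_radius + 1)` square kernel, sum 1.
#' @export
synthesize_psf <- function(synthesized_otf, support_radius = 16L) {
  shp <- dim(synthesized_otf)
  psf <- fftshift(Re(ifft2(synthesized_otf)))
  cy <- floor(shp[1] / 2) + 1; cx <- floor(shp[2] / 2) + 1
  r <- min(support_radius, cy - 1, cx - 1, shp[1] - cy, shp[2] - cx)
  k <- psf[(cy - r):(cy + r), (cx - r):(cx + r)]
  k / sum(k)
}

#' Final deconvolution with the synthesized SIM PSF
#'
#' Richardson-Lucy with the synthesized kernel to suppress the sidelobe
#' artifacts of the fused passband (negative sidelobes of the kernel are
#' clipped; RL needs a non-negative kernel).
#'
#' @param sr_image super-resolved image (non-negative).
#' @param sim_psf kernel from [synthesize_psf()].
#' @param iterations RL iterations (0 = identity).
#' @export
final_deconvolve <- function(sr_image, sim_psf, iterations = 10L) {
  rl_deconvolve(pmax(sr_image, 0), sim_psf, iterations)
}

#' Reconstruct a super-resolved image from a raw pattern stack
#'
#' The end-to-end estimator: per-angle preprocessing and illumination
#' estimation (phase differences by weighted cross-correlation
#' minimization, prior-constrained coarse k search, sub-pixel refinement,
#' phase/modulation extraction), exact order separation, two-step Wiener
#' fusion with notch and apodization on the 2x upsampled grid, synthesized
#' SIM PSF and final RL deconvolution. Deterministic given the inputs.
#'
#' @param stack a [subroi_stack()] with a complete set of
#'   `3 x n_angles` images (angle-major pattern order).
#' @param optics an [optics_model()].
#' @param prior_angles nominal pattern angles in degrees (from the SLM
#'   fringe geometry), one per angle.
#' @param filters a [fusion_filters()].
#' @param pre_rl_iterations RL pre-filter iterations on the
#'   parameter-estimation path (the fusion path stays linear:
#'   background-subtracted and apodized only).
#' @param final_rl_iterations final deconvolution iterations.
#' @param border_width,apod_sigma edge apodization parameters.
#' @param register logical: phase-correlation registration of the stack
#'   against its first image before anything else.
#' @param register_max_freq low-pass radius for registration (see
#'   [register_subrois()]); sensible choice `0.7 / period`.
#' @param fixed_k optional list of per-angle k-vectors (`c(ky, kx)`,
#'   cycles/pixel): skip the k search and re-estimate only phases and
#'   modulation (used by [rolling_reconstruct()] across time points).
#' @param sector_halfwidth prior sector half-width, degrees.
#' @return object of class `parsim_recon`: the 2x super-resolved image,
#'   widefield reference, fused spectrum, synthesized OTF/PSF, per-angle
#'   estimates and QC metrics.
#' @export
sim_reconstruct <- function(stack, optics, prior_angles,
                            filters = fusion_filters(),
                            pre_rl_iterations = 5L, final_rl_iterations = 10L,
                            border_width = 8, apod_sigma = 4,
                            register = FALSE, register_max_freq = NULL,
                            fixed_k = NULL, sector_halfwidth = 2.5) {
  stopifnot(inherits(stack, "subroi_stack"), inherits(optics, "optics_model"))
  n_angles <- length(prior_angles)
  n_needed <- 3L * n_angles
  if (length(stack$images) != n_needed)
    stop("incomplete pattern set: ", length(stack$images), " images for ",
         n_angles, " angles x 3 phases (need ", n_needed, ")")
  want <- cbind(angle = rep(seq_len(n_angles), each = 3), phase = rep(1:3, n_angles))
  ord <- match(paste(want[, 1], want[, 2]),
               paste(stack$labels[, 1], stack$labels[, 2]))
  if (anyNA(ord)) stop("incomplete pattern set: missing (angle, phase) labels")
  stack$images <- stack$images[ord]
  stack$labels <- stack$labels[ord, , drop = FALSE]
  if (register) stack <- register_subrois(stack, max_freq = register_max_freq)

  # estimation path (contrast-enhanced) and linear fusion path
  est_stack <- preprocess_stack(stack, optics, border_width, apod_sigma,
                                rl_iterations = pre_rl_iterations)
  lin_stack <- preprocess_stack(stack, optics, border_width, apod_sigma,
                                rl_iterations = 0L)
  shp <- dim(stack$images[[1]])
  optics_fine <- optics_model(optics$na, optics$wavelength_em,
                              optics$wavelength_ex, optics$pixel_size / 2)
  entries <- list()
  estimates <- vector("list", n_angles)
  conditions <- numeric(n_angles)
  for (a in seq_len(n_angles)) {
    idx <- which(stack$labels[, 1] == a)
    il <- estimate_illumination(est_stack$images[idx], optics, prior_angles[a],
                                sector_halfwidth = sector_halfwidth,
                                fixed_k = if (is.null(fixed_k)) NULL else fixed_k[[a]])
    ph <- il$phase
    ref <- il$estimate
    k <- ref$k
    # linear-path separation with the estimated phases; rescale the side
    # orders by the estimated global phase and modulation
    d_lin <- lapply(lin_stack$images[idx], fft2)
    comps <- separate_orders(d_lin, c(0, ph$phi), m = 1)
    conditions[a] <- comps$condition
    fac_minus <- exp(-1i * ref$global_phase) / max(ref$modulation, 0.05)
    fac_plus <- Conj(fac_minus)
    k_f <- k / 2  # cycles/pixel of the fine grid
    entries <- c(entries, list(
      list(spectrum = upsample_spectrum(comps$order0), k_shift = c(0, 0), m = 1),
      list(spectrum = shift_order(upsample_spectrum(comps$minus * fac_minus), k_f),
           k_shift = k_f, m = ref$modulation),
      list(spectrum = shift_order(upsample_spectrum(comps$plus * fac_plus), -k_f),
           k_shift = -k_f, m = ref$modulation)))
    estimates[[a]] <- list(phase = ph, estimate = ref,
                           prior_angle = prior_angles[a])
  }
  fusion <- fuse_spectra(entries, optics_fine, filters)
  sr_c <- ifft2(fusion$fused)
  imag_ratio <- max(Mod(Im(sr_c))) / max(abs(Re(sr_c)))
  sr <- pmax(Re(sr_c), 0)
  psf <- synthesize_psf(fusion$synthesized_otf)
  sr_dec <- if (final_rl_iterations > 0)
    final_deconvolve(sr, psf, final_rl_iterations) else sr
  wf <- Reduce(`+`, lin_stack$images) / length(lin_stack$images)
  wf_up <- Re(ifft2(upsample_spectrum(fft2(wf))))
  structure(list(sr_image = sr_dec, sr_image_predeconv = sr,
                 widefield = wf_up, fused_spectrum = fusion$fused,
                 synthesized_otf = fusion$synthesized_otf,
                 synthesized_psf = psf,
                 estimates = estimates, optics = optics,
                 qc = list(imag_ratio = imag_ratio,
                           separation_condition = conditions,
                           extended_cutoff = fusion$extended_cutoff,
                           resolution_gain = fusion$extended_cutoff /
                             cutoff_frequency(optics) * 2),
                 filters = filters),
            class = "parsim_recon")
}

#' @export
print.parsim_recon <- function(x, ...) {
  d <- dim(x$sr_image)
  cat(sprintf("SIM reconstruction: %d x %d super-resolved image (2x grid)\n",
              d[1], d[2]))
  cat(sprintf("  extended cutoff %.4f c/px on the fine grid (nominal gain %.2fx), max imag residual %.2e\n",
              x$qc$extended_cutoff, x$qc$resolution_gain, x$qc$imag_ratio))
  cat("Illumination estimates:\n")
  print(coef(x))
  invisible(x)
}

#' @export
summary.parsim_recon <- function(object, ...) {
  print(object)
  cat(sprintf("  separation condition numbers: %s\n",
              paste(signif(object$qc$separation_condition, 4), collapse = ", ")))
  invisible(object)
}

#' Illumination parameter estimates of a reconstruction
#' @param object a `parsim_recon`.
#' @param ... unused.
#' @return matrix, one row per pattern angle.
#' @export
coef.parsim_recon <- function(object, ...) {
  t(vapply(object$estimates, function(e)
    c(ky = e$estimate$k[1], kx = e$estimate$k[2],
      magnitude = e$estimate$magnitude, angle_deg = e$estimate$angle,
      phi21 = e$phase$phi[1], phi31 = e$phase$phi[2],
      global_phase = e$estimate$global_phase,
      modulation = e$estimate$modulation), numeric(8)))
}

#' @export
plot.parsim_recon <- function(x, which = c("sr", "widefield", "spectrum", "psf"),
                              ...) {
  which <- match.arg(which)
  img <- switch(which,
                sr = x$sr_image,
                widefield = x$widefield,
                spectrum = log1p(Mod(fftshift(x$fused_spectrum))),
                psf = x$synthesized_psf)
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(img) / ncol(img),
                  main = paste("parsim:", which), ...)
  invisible(x)
}

#' Rolling (sliding-window) reconstruction of a sub-image time series
#'
#' Reconstructs a sliding window of one full pattern set advanced by
#' `step` sub-images, the newest images replacing the oldest of the same
#' (angle, phase), multiplying the output frame rate by
#' `set_size / step`. k-vectors are estimated on the first window and
#' reused (phases and modulation are refreshed per window: vibration
#' perturbs phase much more than fringe period); set `reestimate_k = TRUE`
#' to redo the full search each window.
#'
#' @param images list of sub-images in acquisition order (pattern order
#'   repeating over time: angle-major, 3 phases per angle).
#' @param optics an [optics_model()].
#' @param prior_angles nominal pattern angles (degrees).
#' @param step window advance in sub-images; must divide the set size.
#' @param t_i optional sub-frame time (ms) to timestamp outputs.
#' @param reestimate_k logical, full k search every window.
#' @param ... passed to [sim_reconstruct()].
#' @return list of class `parsim_rolling`: `frames` (list of
#'   `parsim_recon`), `timestamps` (ms, window start), `step`, `set_size`.
#' @export
rolling_reconstruct <- function(images, optics, prior_angles, step,
                                t_i = NA, reestimate_k = FALSE, ...) {
  n_angles <- length(prior_angles)
  set_size <- 3L * n_angles
  n <- length(images)
  if (set_size %% step != 0)
    stop("step ", step, " does not divide the pattern-set size ", set_size)
  if (n < set_size) stop("need at least one full pattern set (", set_size, " images)")
  starts <- seq(1L, n - set_size + 1L, by = step)
  labels_cycle <- cbind(angle = rep(seq_len(n_angles), each = 3),
                        phase = rep(1:3, n_angles))
  frames <- vector("list", length(starts))
  fixed_k <- NULL
  for (i in seq_along(starts)) {
    idx <- starts[i] + 0:(set_size - 1L)
    labels <- labels_cycle[(idx - 1L) %% set_size + 1L, , drop = FALSE]
    stk <- subroi_stack(images[idx], labels = labels)
    frames[[i]] <- sim_reconstruct(stk, optics, prior_angles,
                                   fixed_k = if (reestimate_k) NULL else fixed_k,
                                   ...)
    if (i == 1L && !reestimate_k)
      fixed_k <- lapply(frames[[1]]$estimates, function(e) e$estimate$k)
  }
  structure(list(frames = frames,
                 timestamps = if (is.na(t_i)) rep(NA_real_, length(starts))
                 else (starts - 1) * t_i,
                 step = step, set_size = set_size),
            class = "parsim_rolling")
}

#' @export
print.parsim_rolling <- function(x, ...) {
  cat(sprintf("Rolling reconstruction: %d frames (window %d, step %d)\n",
              length(x$frames), x$set_size, x$step))
  invisible(x)
}
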