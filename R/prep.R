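# Preprocessing: full frames -> registered, contrast-enhanced per-pattern
# sub-images (crop, rigid registration, background subtraction, edge
# apodization, Richardson-Lucy pre-filtering).

#' Sub-ROI stack
#'
#' Ordered per-pattern sub-images plus their (angle, phase) labels,
#' per-image applied/estimated shifts, background estimates and provenance.
#'
#' @param images list of equal-shape matrices, pattern order.
#' @param labels `n x 2` matrix of (angle, phase) indices.
#' @param shifts `n x 2` matrix of shifts (dy, dx) associated with each
#'   image (applied by the instrument, or estimated and removed).
#' @param provenance optional source frame indices.
#' @export
subroi_stack <- function(images, labels = NULL, shifts = NULL, provenance = NULL) {
  n <- length(images)
  stopifnot(n >= 1)
  d <- vapply(images, dim, integer(2))
  if (any(d[1, ] != d[1, 1]) || any(d[2, ] != d[2, 1]))
    stop("all sub-images must share one shape")
  if (is.null(labels)) {
    n_ang <- n %/% 3L
    labels <- cbind(angle = rep(seq_len(n_ang), each = 3),
                    phase = rep(1:3, n_ang))
  }
  if (is.null(shifts)) shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  if (anyDuplicated(labels)) stop("(angle, phase) labels must be unique")
  stopifnot(all(is.finite(shifts)))
  structure(list(images = images, labels = labels, shifts = shifts,
                 background = rep(NA_real_, n), provenance = provenance),
            class = "subroi_stack")
}

#' @export
print.subroi_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Sub-ROI stack: %d images of %d x %d (%d angles x 3 phases)\n",
              length(x$images), d[1], d[2], max(x$labels[, 1])))
  invisible(x)
}

#' Crop sub-ROIs out of a full frame
#'
#' Extracts the six layout rectangles (half-open pixel intervals, no
#' resampling) and orders them by pattern index via the layout's scan
#' order.
#'
#' @param frame full-frame matrix.
#' @param layout the [frame_layout()] used at acquisition.
#' @return a [subroi_stack()] in pattern order.
#' @export
crop_subrois <- function(frame, layout) {
  stopifnot(is.matrix(frame), inherits(layout, "frame_layout"))
  imgs <- vector("list", 6)
  for (p in 1:6) {
    r <- layout$rects[layout$scan_order[p], ]
    if (r["y0"] < 0 || r["x0"] < 0 || r["y1"] > nrow(frame) || r["x1"] > ncol(frame))
      stop(sprintf("rectangle [%g,%g)x[%g,%g) extends past the %d x %d frame",
                   r["y0"], r["y1"], r["x0"], r["x1"], nrow(frame), ncol(frame)))
    imgs[[p]] <- frame[(r["y0"] + 1):r["y1"], (r["x0"] + 1):r["x1"], drop = FALSE]
  }
  subroi_stack(imgs, provenance = rep(1L, 6))
}

# Phase-correlation shift estimate (reference -> image) with sub-pixel
# refinement by locally upsampled cross-correlation (matrix-multiply DFT).
# Returns c(dy, dx) such that image ~ reference translated by (dy, dx).
phasecor_shift <- function(reference, image, upsample = 100, max_freq = NULL) {
  nr <- nrow(reference); nc <- ncol(reference)
  FR <- fft2(reference); FI <- fft2(image)
  cross <- FI * Conj(FR)
  if (!is.null(max_freq)) cross[freq_radius(nr, nc) > max_freq] <- 0
  cc <- abs(ifft2(cross))
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  shift <- ifelse(peak > c(nr, nc) / 2, peak - c(nr, nc), peak)
  if (upsample <= 1) return(as.numeric(shift))
  # refine in a 1.5 px neighborhood at 1/upsample resolution
  win <- ceiling(upsample * 1.5)
  off <- shift - win / 2 / upsample
  fy <- fft_freq(nr) * nr; fx <- fft_freq(nc) * nc
  steps <- (0:win) / upsample
  ey <- exp(2i * pi * outer(off[1] + steps, fy) / nr)   # (win+1) x nr
  ex <- exp(2i * pi * outer(fx, off[2] + steps) / nc)   # nc x (win+1)
  cc_up <- abs(ey %*% cross %*% ex)
  pk <- arrayInd(which.max(cc_up), dim(cc_up)) - 1L
  as.numeric(off + pk / upsample)
}

#' Register a sub-ROI stack by phase correlation
#'
#' Estimates the rigid translation of every image (phase correlation with
#' sub-pixel refinement on an upsampled local cross-correlation), removes
#' it by Fourier translation and records the estimates. Because the images
#' carry different illumination phases of one scene, a direct pairwise
#' correlation is biased along the fringe direction; after the initial
#' pass the estimates are therefore refined against the leave-one-out mean
#' of the aligned stack, in which the sinusoidal modulation largely
#' cancels. Constant (degenerate) images are skipped with a warning.
#'
#' @param stack a [subroi_stack()].
#' @param reference index of the reference image (default 1, the first
#'   phase of the first angle).
#' @param upsample sub-pixel refinement factor.
#' @param max_freq optional low-pass radius (cycles/pixel) for the
#'   cross-power spectrum; registering different illumination phases of
#'   one scene is biased by the fringe component, so restrict the
#'   correlation to frequencies below the fringe (e.g. `0.7/period`).
#' @param refine_passes refinement iterations against the leave-one-out
#'   aligned mean (0 = plain pairwise registration).
#' @return the stack with images aligned and `shifts` holding the
#'   estimated (removed) shifts (relative to the reference image).
#' @export
register_subrois <- function(stack, reference = 1L, upsample = 100,
                             max_freq = NULL, refine_passes = 2L) {
  stopifnot(inherits(stack, "subroi_stack"), length(stack$images) >= 2)
  n <- length(stack$images)
  ref <- stack$images[[reference]]
  degenerate <- vapply(stack$images, function(im) stats::sd(im) == 0, logical(1))
  if (any(degenerate))
    warning("constant image; registration skipped for image ",
            paste(which(degenerate), collapse = ", "))
  s <- matrix(0, n, 2)
  if (!degenerate[reference]) {
    for (i in seq_len(n)) {
      if (i == reference || degenerate[i]) next
      s[i, ] <- phasecor_shift(ref, stack$images[[i]], upsample, max_freq)
    }
    for (pass in seq_len(refine_passes)) {
      aligned <- lapply(seq_len(n), function(i)
        fourier_translate(stack$images[[i]], -s[i, ]))
      total <- Reduce(`+`, aligned)
      for (i in seq_len(n)) {
        if (degenerate[i]) next
        loo <- (total - aligned[[i]]) / (n - 1)
        s[i, ] <- s[i, ] + phasecor_shift(loo, aligned[[i]], upsample, max_freq)
      }
      s <- sweep(s, 2, s[reference, ])  # keep the reference at zero shift
    }
  }
  for (i in seq_len(n)) {
    if (any(s[i, ] != 0))
      stack$images[[i]] <- fourier_translate(stack$images[[i]], -s[i, ])
    stack$shifts[i, ] <- s[i, ]
  }
  stack
}

#' Estimate the scalar background of an image
#'
#' The mode of the intensity histogram, estimated as the density peak of
#' the lower 80% of pixel values: unbiased for a symmetric-noise
#' background with sparse bright structure on top (a trimmed quantile
#' statistic would sit systematically below the background mean). For an
#' image with no true background region the statistic is still returned
#' (callers may clamp).
#'
#' @param image numeric matrix.
#' @return scalar background estimate (counts).
#' @export
estimate_background <- function(image) {
  stopifnot(length(image) > 0)
  v <- image[image <= stats::quantile(image, 0.8)]
  if (max(v) == min(v)) return(v[1])
  d <- stats::density(v, n = 512)
  d$x[which.max(d$y)]
}

#' Subtract a background level, clipping at zero
#' @param image numeric matrix.
#' @param background scalar; default from [estimate_background()].
#' @export
subtract_background <- function(image, background = estimate_background(image)) {
  pmax(image - background, 0)
}

#' Taper image borders toward the background level
#'
#' Suppresses the spectral leakage of the periodization discontinuity: a
#' Gaussian-smoothed taper (truncated, renormalized Gaussian CDF ramp)
#' takes each border pixel smoothly from 0 at the edge to exactly 1 at
#' `border_width`, so interior pixels are bit-identical before and after.
#' Apply after background subtraction so the borders blend toward 0.
#'
#' @param image numeric matrix.
#' @param border_width taper width, pixels (0 = identity).
#' @param sigma Gaussian smoothing scale of the ramp, pixels.
#' @return tapered image.
#' @export
apodize_edges <- function(image, border_width = 16, sigma = 8) {
  stopifnot(border_width >= 0, sigma > 0)
  if (border_width == 0) return(image)
  if (border_width >= min(dim(image)) / 2)
    stop("border_width ", border_width, " too large for a ",
         nrow(image), " x ", ncol(image), " image")
  ramp <- function(d) {
    t <- (stats::pnorm((d - border_width / 2) / sigma) -
            stats::pnorm(-border_width / 2 / sigma)) /
      (stats::pnorm(border_width / 2 / sigma) -
         stats::pnorm(-border_width / 2 / sigma))
    pmin(pmax(t, 0), 1)
  }
  dist1 <- function(n) pmin(seq_len(n) - 1, n - seq_len(n))
  ty <- ifelse(dist1(nrow(image)) >= border_width, 1, ramp(dist1(nrow(image))))
  tx <- ifelse(dist1(ncol(image)) >= border_width, 1, ramp(dist1(ncol(image))))
  image * outer(ty, tx, pmin)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative RL updates with FFT convolution and reflective
#' padding; non-negativity is preserved and, with a normalized kernel,
#' total intensity is conserved to about 1e-3 relative.
#'
#' @param image non-negative matrix (negative pixels, e.g. after background
#'   subtraction, are clipped to 0 with a warning).
#' @param psf centered kernel (odd-sized small matrix or full image size),
#'   normalized to sum 1; tiny negative sidelobes are clipped.
#' @param iterations RL iterations (0 = identity).
#' @return deconvolved image.
#' @export
rl_deconvolve <- function(image, psf, iterations = 5L) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(image)
  if (any(image < 0)) {
    warning("negative pixels clipped to 0 before RL deconvolution")
    image <- pmax(image, 0)
  }
  psf <- pmax(psf, 0)
  if (abs(sum(psf) - 1) > 1e-6) psf <- psf / sum(psf)
  pad <- max(ceiling(dim(psf) / 2))
  pad <- min(pad, nrow(image) - 1, ncol(image) - 1)
  padded <- pad_reflect(image, pad)
  otf <- embed_psf(psf, dim(padded))
  est <- padded
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    conv <- Re(ifft2(fft2(est) * otf))
    ratio <- padded / pmax(conv, eps)
    est <- est * Re(ifft2(fft2(ratio) * Conj(otf)))
    est <- pmax(est, 0)
  }
  est[(pad + 1):(pad + nrow(image)), (pad + 1):(pad + ncol(image))]
}

# Reflective padding by `pad` pixels on every side.
pad_reflect <- function(image, pad) {
  if (pad == 0) return(image)
  ri <- c(rev(seq_len(pad) + 1), seq_len(nrow(image)),
          nrow(image) - seq_len(pad))
  ci <- c(rev(seq_len(pad) + 1), seq_len(ncol(image)),
          ncol(image) - seq_len(pad))
  image[ri, ci]
}

# Embed a centered small kernel into a full-size unshifted OTF.
embed_psf <- function(psf, shape) {
  big <- matrix(0, shape[1], shape[2])
  pr <- nrow(psf); pc <- ncol(psf)
  cy <- floor(pr / 2) + 1; cx <- floor(pc / 2) + 1
  r0 <- floor(shape[1] / 2) + 1 - cy; c0 <- floor(shape[2] / 2) + 1 - cx
  big[r0 + seq_len(pr), c0 + seq_len(pc)] <- psf
  fft2(ifftshift(big))
}

#' Preprocess a sub-ROI stack for parameter estimation
#'
#' Background subtraction, edge apodization and (optionally) a few
#' Richardson-Lucy iterations with the theoretical system PSF to raise the
#' in-band spectral contrast before illumination-parameter estimation.
#'
#' @param stack a [subroi_stack()].
#' @param optics an [optics_model()] (for the RL PSF).
#' @param border_width,sigma apodization parameters (see [apodize_edges()]).
#' @param rl_iterations RL pre-filter iterations (0 disables).
#' @return the stack with processed images and `background` filled in.
#' @export
preprocess_stack <- function(stack, optics, border_width = 8, sigma = 4,
                             rl_iterations = 5L) {
  stopifnot(inherits(stack, "subroi_stack"))
  psf <- if (rl_iterations > 0)
    psf_small(optics, dim(stack$images[[1]])) else NULL
  for (i in seq_along(stack$images)) {
    bg <- estimate_background(stack$images[[i]])
    img <- subtract_background(stack$images[[i]], bg)
    img <- apodize_edges(img, border_width, sigma)
    if (rl_iterations > 0) img <- rl_deconvolve(img, psf, rl_iterations)
    stack$images[[i]] <- img
    stack$background[i] <- bg
  }
  stack
}

# Compact theoretical PSF kernel (odd-sized) for RL pre-filtering.
psf_small <- function(optics, shape, radius = 12L) {
  full <- psf_from_optics(optics, shape)
  cy <- floor(shape[1] / 2) + 1; cx <- floor(shape[2] / 2) + 1
  r <- min(radius, cy - 1, cx - 1, shape[1] - cy, shape[2] - cx)
  k <- full[(cy - r):(cy + r), (cx - r):(cx + r)]
  k / sum(k)
}
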