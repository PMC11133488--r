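# Quantification utilities: SNR estimation on raw frames, FWHM/resolution
# measurement, and tip displacement/velocity statistics for membrane
# tubulation tracks.

#' SNR of a raw image from noise and signal regions
#'
#' The noise region (background only) gives `mu_noise` and its variance
#' `MSE_noise`; the signal region gives `mu_signal`; then
#' `Signal = mu_signal - mu_noise` and
#' `SNR = 10 log10(Signal / MSE_noise)` in dB.
#'
#' @param image numeric matrix.
#' @param noise_region,signal_region logical masks (same shape as `image`)
#'   or `n x 2` matrices of (row, col) indices; must be non-empty and
#'   disjoint.
#' @return list of class `snr_report`: `mu_noise`, `mse_noise`,
#'   `mu_signal`, `signal`, `snr_db` (`NA` with `failed = TRUE` when the
#'   signal estimate is not positive).
#' @examples
#' img <- matrix(10, 20, 20); img[5:10, 5:10] <- 100
#' noise <- col(img) > 12; signal <- img == 100
#' # degenerate: constant noise region errors
#' @export
estimate_snr <- function(image, noise_region, signal_region) {
  as_idx <- function(r) {
    if (is.logical(r)) which(r) else {
      stopifnot(is.matrix(r), ncol(r) == 2)
      (r[, 2] - 1) * nrow(image) + r[, 1]
    }
  }
  ni <- as_idx(noise_region); si <- as_idx(signal_region)
  if (length(ni) == 0 || length(si) == 0) stop("regions must be non-empty")
  if (length(intersect(ni, si)) > 0) stop("noise and signal regions overlap")
  nv <- image[ni]; sv <- image[si]
  mu_noise <- mean(nv)
  mse_noise <- mean((nv - mu_noise)^2)
  if (mse_noise == 0) stop("constant noise region: MSE_noise is zero")
  mu_signal <- mean(sv)
  signal <- mu_signal - mu_noise
  failed <- signal <= 0
  structure(list(mu_noise = mu_noise, mse_noise = mse_noise,
                 mu_signal = mu_signal, signal = signal,
                 snr_db = if (failed) NA_real_ else 10 * log10(signal / mse_noise),
                 failed = failed,
                 n_noise = length(ni), n_signal = length(si)),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf("SNR: %s dB  (signal %.3f = %.3f - %.3f; MSE_noise %.3f)\n",
              if (is.na(x$snr_db)) "undefined" else sprintf("%.2f", x$snr_db),
              x$signal, x$mu_signal, x$mu_noise, x$mse_noise))
  invisible(x)
}

#' Averaged SNR of an image stack
#'
#' Per-image SNRs averaged arithmetically; the averaged signal and
#' averaged noise (MSE) of the stack are the means of the per-image
#' values. Images whose per-image estimate fails (non-positive signal or
#' constant noise region) are listed, excluded and counted.
#'
#' @param stack list of images (or a [subroi_stack()]).
#' @param noise_region,signal_region masks applied to every image.
#' @return list of class `snr_report` with `snr_db`, `signal`,
#'   `mse_noise` (stack averages), `per_image`, `n_failed`, `failed_idx`.
#' @export
stack_snr <- function(stack, noise_region, signal_region) {
  imgs <- if (inherits(stack, "subroi_stack")) stack$images else stack
  stopifnot(length(imgs) >= 1)
  reports <- vector("list", length(imgs))
  ok <- logical(length(imgs))
  for (i in seq_along(imgs)) {
    reports[[i]] <- tryCatch(estimate_snr(imgs[[i]], noise_region, signal_region),
                             error = function(e) structure(list(failed = TRUE,
                                                                error = conditionMessage(e)),
                                                           class = "snr_report"))
    ok[i] <- !isTRUE(reports[[i]]$failed)
  }
  if (!any(ok)) stop("every image in the stack failed SNR estimation")
  gv <- function(f) mean(vapply(reports[ok], function(r) r[[f]], numeric(1)))
  structure(list(snr_db = gv("snr_db"), signal = gv("signal"),
                 mse_noise = gv("mse_noise"), mu_noise = gv("mu_noise"),
                 mu_signal = gv("mu_signal"),
                 per_image = reports, n_failed = sum(!ok),
                 failed_idx = which(!ok), failed = FALSE),
            class = "snr_report")
}

#' FWHM of a point image by Gaussian profile fit
#'
#' Extracts a 1-D line profile through a point (horizontal, vertical, or
#' at an arbitrary angle with bilinear sampling), fits
#' `A exp(-(x - mu)^2 / (2 sigma^2)) + c` by least squares and returns
#' `FWHM = 2 sqrt(2 log 2) sigma x pixel_size`.
#'
#' @param image numeric matrix.
#' @param point `c(row, col)` (1-based) near the local maximum.
#' @param pixel_size nm/pixel of this grid.
#' @param axis `"x"`, `"y"`, or a numeric angle in degrees.
#' @param halfwidth profile half-length, pixels.
#' @return list: `fwhm_nm`, `fwhm_px`, `sigma_px`, `center`, `profile`,
#'   `converged`.
#' @examples
#' g <- outer(dnorm(1:41, 21, 2), dnorm(1:41, 21, 2))
#' measure_fwhm(g, c(21, 21), pixel_size = 65)$fwhm_nm  # ~306
#' @export
measure_fwhm <- function(image, point, pixel_size = 65, axis = "x",
                         halfwidth = 10) {
  stopifnot(length(point) == 2)
  n <- 2 * halfwidth + 1
  t_off <- seq(-halfwidth, halfwidth)
  if (identical(axis, "x")) { dy <- 0; dx <- 1 }
  else if (identical(axis, "y")) { dy <- 1; dx <- 0 }
  else { dy <- sin(axis * pi / 180); dx <- cos(axis * pi / 180) }
  ys <- point[1] + t_off * dy; xs <- point[2] + t_off * dx
  prof <- bilinear_sample(image, ys, xs)
  keep <- is.finite(prof)
  prof <- prof[keep]; tt <- t_off[keep]
  if (length(prof) < 5 || stats::sd(prof) == 0)
    return(list(fwhm_nm = NA_real_, fwhm_px = NA_real_, sigma_px = NA_real_,
                center = NA_real_, profile = prof, converged = FALSE))
  a0 <- max(prof) - min(prof); c0 <- min(prof)
  mu0 <- tt[which.max(prof)]
  s0 <- max(1, sum(prof - c0 > a0 / 2) / 2.3548)
  fn <- function(p) sum((p[1] * exp(-(tt - p[2])^2 / (2 * p[3]^2)) + p[4] - prof)^2)
  fit <- stats::optim(c(a0, mu0, s0, c0), fn, method = "L-BFGS-B",
                      lower = c(1e-9, min(tt), 0.3, -Inf),
                      upper = c(Inf, max(tt), length(tt), Inf))
  converged <- fit$convergence == 0 && fit$par[1] > 3 * stats::sd(prof - mean(prof)) / 2
  sigma <- fit$par[3]
  list(fwhm_nm = if (converged) 2 * sqrt(2 * log(2)) * sigma * pixel_size else NA_real_,
       fwhm_px = 2 * sqrt(2 * log(2)) * sigma, sigma_px = sigma,
       center = fit$par[2], profile = prof, converged = converged)
}

# Bilinear interpolation at fractional (row, col) positions; NA outside.
bilinear_sample <- function(image, ys, xs) {
  nr <- nrow(image); nc <- ncol(image)
  out <- rep(NA_real_, length(ys))
  for (i in seq_along(ys)) {
    y <- ys[i]; x <- xs[i]
    if (y < 1 || y > nr || x < 1 || x > nc) next
    y0 <- floor(y); x0 <- floor(x)
    y1 <- min(y0 + 1, nr); x1 <- min(x0 + 1, nc)
    fy <- y - y0; fx <- x - x0
    out[i] <- image[y0, x0] * (1 - fy) * (1 - fx) + image[y1, x0] * fy * (1 - fx) +
      image[y0, x1] * (1 - fy) * fx + image[y1, x1] * fy * fx
  }
  out
}

#' Tip displacement, direction and velocity statistics of a track
#'
#' Projects frame-to-frame tip motion onto the running tubulation axis
#' (principal axis of a trailing window of positions, oriented
#' consistently along the track), labels each step forward / backward /
#' static with a dead-band, converts to velocities in um/s, and
#' recomputes the velocities on the track subsampled by `step` (the
#' averaged velocity `V'`).
#'
#' @param track data frame with columns `t_ms`, `y_px`, `x_px`
#'   (timestamps strictly increasing).
#' @param pixel_size nm/pixel.
#' @param step subsampling factor for `V'` (e.g. 25 for 7.35 ms ->
#'   183.8 ms sampling).
#' @param dead_band static-label threshold, pixels per step.
#' @param axis_window trailing positions used for the running axis.
#' @return list of class `track_stats`: `displacement_px` (signed, per
#'   step), `direction` (factor forward/backward/static), `velocity`
#'   (um/s), `downsampled` (list with `t_ms`, `velocity`), `step`.
#' @export
track_stats <- function(track, pixel_size = 65, step = 25L, dead_band = 0.5,
                        axis_window = 10L) {
  stopifnot(all(c("t_ms", "y_px", "x_px") %in% names(track)))
  if (nrow(track) < 2) stop("a track needs at least 2 points")
  if (any(diff(track$t_ms) <= 0)) stop("timestamps must be strictly increasing")
  core <- function(tr) {
    n <- nrow(tr)
    disp <- numeric(n - 1)
    axis_prev <- NULL
    for (i in seq_len(n - 1)) {
      lo <- max(1, i + 1 - axis_window)
      pts <- cbind(tr$y_px[lo:(i + 1)], tr$x_px[lo:(i + 1)])
      if (nrow(unique(pts)) < 2) {
        ax <- if (is.null(axis_prev)) c(0, 1) else axis_prev
      } else {
        pc <- stats::prcomp(pts)
        ax <- pc$rotation[, 1]
      }
      if (!is.null(axis_prev) && sum(ax * axis_prev) < 0) ax <- -ax
      axis_prev <- ax
      stp <- c(tr$y_px[i + 1] - tr$y_px[i], tr$x_px[i + 1] - tr$x_px[i])
      disp[i] <- sum(stp * ax)
    }
    dt_s <- diff(tr$t_ms) / 1000
    vel <- disp * pixel_size / 1000 / dt_s
    list(displacement_px = disp,
         direction = factor(ifelse(abs(disp) < dead_band, "static",
                                   ifelse(disp > 0, "forward", "backward")),
                            levels = c("forward", "backward", "static")),
         velocity = vel, t_ms = tr$t_ms[-1])
  }
  full <- core(track)
  sub <- track[seq(1, nrow(track), by = step), , drop = FALSE]
  down <- if (nrow(sub) >= 2) core(sub) else
    list(displacement_px = numeric(0), velocity = numeric(0), t_ms = numeric(0))
  structure(c(full, list(downsampled = down, step = as.integer(step),
                         pixel_size = pixel_size)),
            class = "track_stats")
}

#' @export
print.track_stats <- function(x, ...) {
  cat(sprintf("Track: %d steps; |V| max %.2f um/s (downsampled x%d: max %.2f um/s)\n",
              length(x$velocity), max(abs(x$velocity)), x$step,
              if (length(x$downsampled$velocity)) max(abs(x$downsampled$velocity)) else NA))
  print(table(x$direction))
  invisible(x)
}

#' Read a track from CSV
#'
#' Expects columns `frame`, `t_ms`, `x_px`, `y_px` (extra columns kept).
#' @param path CSV file.
#' @export
read_track <- function(path) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("t_ms", "x_px", "y_px") %in% names(tr)))
  tr
}
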