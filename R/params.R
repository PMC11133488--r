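# Illumination-parameter estimation from low-SNR phase triplets:
# zero-order-free difference spectra, phase-difference estimation by
# minimizing the weighted cross-correlation of the separated +/-1 orders,
# spectral separation by exact inversion of the phase-mixing matrix,
# prior-constrained coarse k-vector search on a ring mask, and sub-pixel
# refinement by continuous cross-correlation with phase-ramp shifts.
#
# Mixing model (forward-FFT sign convention): the image spectrum under
# illumination phase phi is
#   D(k) = (I0/2) [ S(k)H(k) + (m/2) e^{+i phi} S(k-k0)H(k)
#                            + (m/2) e^{-i phi} S(k+k0)H(k) ] + noise + bg.

#' Zero-order-free difference spectra
#'
#' Differences of the second and third phase spectra against the first;
#' the zero-order term (and any phase-independent background) cancels
#' exactly, leaving only +/-1-order content.
#'
#' @param d_fft list of three same-shape complex spectra (one angle,
#'   phases 1..3).
#' @return list `d21`, `d31`.
#' @export
difference_spectra <- function(d_fft) {
  stopifnot(length(d_fft) == 3)
  d <- lapply(d_fft, function(x) { stopifnot(is.complex(x) || is.numeric(x)); x })
  if (!all(vapply(d, function(x) identical(dim(x), dim(d[[1]])), logical(1))))
    stop("spectra shapes differ")
  list(d21 = d[[2]] - d[[1]], d31 = d[[3]] - d[[1]])
}

#' Weight function for the phase-difference objective
#'
#' Default `w(k)`: indicator of the ring `ring[1]..ring[2]` times the OTF
#' cutoff, multiplied by OTF^2. Vanishes at DC (suppressing the residual
#' zero-order contribution) and beyond the passband.
#'
#' @param optics an [optics_model()].
#' @param shape spectrum shape.
#' @param ring inner/outer radius as multiples of the cutoff.
#' @return non-negative matrix (unshifted frequency layout).
#' @export
build_weight <- function(optics, shape, ring = c(0.3, 1.0)) {
  kc <- cutoff_frequency(optics)
  kr <- freq_radius(shape[1], shape[2])
  h <- otf_matrix(optics, shape)
  (kr >= ring[1] * kc & kr <= ring[2] * kc) * h^2
}

#' Phase mixing matrix of a three-phase triplet
#'
#' @param phases length-3 illumination phases (radians).
#' @param m modulation depth.
#' @return list with the 3 x 3 complex matrix `m_matrix`, its inverse and
#'   its condition number.
#' @export
separation_matrix <- function(phases, m) {
  stopifnot(length(phases) == 3, m >= 0)
  M <- cbind(1, m / 2 * exp(1i * phases), m / 2 * exp(-1i * phases))
  cn <- kappa(M, exact = TRUE)
  if (!is.finite(cn) || cn > 1e6)
    stop("phase mixing matrix is singular or ill-conditioned (condition ",
         format(cn, digits = 3), "): phases must be distinct modulo 2pi and m > 0")
  list(m_matrix = M, inverse = solve(M), condition = cn)
}

#' Separate the 0 and +/-1 spectral orders
#'
#' Exact per-frequency inversion of the phase mixing matrix (no
#' regularization): returns the unshifted components
#' `S(k)H(k)`, `S(k-k0)H(k)`, `S(k+k0)H(k)` on the scale set by `i0`
#' (with `i0` the true amplitude and true phases/m, the components come
#' out exactly on the sample-spectrum scale).
#'
#' @param d_fft list of three spectra (one angle, phases 1..3).
#' @param phases length-3 phases used to build the mixing matrix (for
#'   estimation use `c(0, phi_diffs)`).
#' @param m modulation depth used in the matrix (1 during estimation).
#' @param i0 illumination amplitude scale (2 leaves the `M^-1` result
#'   unscaled).
#' @return list `order0`, `minus` (the `S(k-k0)H` component), `plus`,
#'   plus the matrix `condition`.
#' @export
separate_orders <- function(d_fft, phases, m, i0 = 2) {
  stopifnot(length(d_fft) == 3, i0 > 0)
  sm <- separation_matrix(phases, m)
  inv <- sm$inverse * (2 / i0)
  comp <- function(j) inv[j, 1] * d_fft[[1]] + inv[j, 2] * d_fft[[2]] +
    inv[j, 3] * d_fft[[3]]
  list(order0 = comp(1), minus = comp(2), plus = comp(3),
       condition = sm$condition)
}

# 2x2 difference-mixing separation at candidate phase differences; returns
# the candidate side components (A ~ S(k-k0)H, B ~ S(k+k0)H up to scale).
separate_differences <- function(diffs, phi) {
  a <- exp(1i * phi[1]) - 1; b <- exp(-1i * phi[1]) - 1
  cc <- exp(1i * phi[2]) - 1; d <- exp(-1i * phi[2]) - 1
  det <- a * d - b * cc
  if (abs(det) < 1e-9) return(NULL)
  list(A = (d * diffs$d21 - b * diffs$d31) / det,
       B = (-cc * diffs$d21 + a * diffs$d31) / det)
}

#' Estimate the illumination phase differences of one angle
#'
#' In the ideal model the separated spectral orders are mutually
#' independent, so the weighted cross-correlations among the candidate
#' components (zero and both first orders) are jointly minimal when the
#' separation uses the true phase differences; the zero-order terms anchor
#' the objective against the spurious exact zeros a two-order correlation
#' alone admits. The weighted correlations of every candidate separation
#' are closed forms in one precomputed 3 x 3 Gram matrix, so a dense
#' deterministic 2-D grid over both differences (`phi2` in `(pi/3, pi)`,
#' `phi3` in `(2pi/3, 2pi)`) costs only 3 x 3 algebra per point; a
#' Nelder-Mead polish follows. Deterministic, no random seeds.
#'
#' @param d_fft list of three spectra (one angle).
#' @param weight weight matrix from [build_weight()].
#' @param search search interval for the first difference (radians); the
#'   second spans twice it.
#' @param grid_n coarse grid size along `phi2` (twice along `phi3`).
#' @param refine logical: Nelder-Mead polish of both differences.
#' @return list with `phi` (the two phase differences `phi2 - phi1`,
#'   `phi3 - phi1`), `objective` (final normalized cross-correlation) and
#'   the coarse `trace` (phi grid + objective values).
#' @export
estimate_phase_differences <- function(d_fft, weight,
                                       search = c(pi / 3, pi),
                                       grid_n = 48L, refine = TRUE) {
  stopifnot(length(d_fft) == 3)
  diffs <- difference_spectra(d_fft)
  power <- sum(weight * (Mod(diffs$d21)^2 + Mod(diffs$d31)^2))
  if (power <= 0 || !is.finite(power))
    stop("no modulation detected: difference spectra carry no weighted power")
  # weighted Gram matrix of the three spectra: every candidate separation's
  # cross-correlations are closed forms in it, so the search costs 3x3
  # algebra per candidate instead of full-grid sums
  G <- matrix(0 + 0i, 3, 3)
  for (i in 1:3) for (j in i:3) {
    G[i, j] <- sum(weight * d_fft[[i]] * Conj(d_fft[[j]]))
    if (j > i) G[j, i] <- Conj(G[i, j])
  }
  obj <- function(phi) {
    M <- cbind(1, 0.5 * exp(1i * c(0, phi)), 0.5 * exp(-1i * c(0, phi)))
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) return(Inf)
    Gc <- Minv %*% G %*% Conj(t(Minv))
    n <- Re(diag(Gc))
    if (any(n <= 0) || any(!is.finite(n))) return(Inf)
    Mod(Gc[1, 2])^2 / (n[1] * n[2]) + Mod(Gc[1, 3])^2 / (n[1] * n[3]) +
      Mod(Gc[2, 3])^2 / (n[2] * n[3])
  }
  eps <- 1e-2
  g2 <- seq(search[1] + eps, search[2] - eps, length.out = grid_n)
  g3 <- seq(2 * search[1] + eps, 2 * search[2] - eps, length.out = 2L * grid_n)
  vals <- outer(g2, g3, Vectorize(function(a, b) obj(c(a, b))))
  if (min(vals) > 0.3)
    stop("degenerate phase triplet: separated orders cannot be decorrelated ",
         "(equal phases or vanishing modulation)")
  ij <- arrayInd(which.min(vals), dim(vals))
  phi <- c(g2[ij[1]], g3[ij[2]])
  objective <- min(vals)
  if (refine) {
    fit <- stats::optim(phi, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    phi <- fit$par
    objective <- fit$value
  }
  list(phi = phi, objective = objective,
       trace = list(phi2 = g2, phi3 = g3, objective = vals))
}

# Signed angular difference in degrees, in (-180, 180].
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Coarse (pixel-accurate) illumination k-vector search
#'
#' Peak of the separated first-order spectrum magnitude restricted to a
#' ring of `ring[1]..ring[2]` times the OTF cutoff intersected with a
#' `+/- sector_halfwidth` degree sector around the prior pattern angle
#' (known from the fringes loaded on the SLM).
#'
#' @param spectrum separated `minus` component (unshifted layout); its peak
#'   sits at `+k_theta`.
#' @param optics an [optics_model()].
#' @param prior_angle nominal pattern angle, degrees.
#' @param sector_halfwidth half-width of the angular sector, degrees.
#' @param ring ring radii as multiples of the cutoff.
#' @return list of class `k_vector`: `k = c(ky, kx)` (cycles/pixel),
#'   `angle`, `magnitude`, `peak_value`, `precision = "pixel"`,
#'   `on_boundary`, `n_search` (mask size, for audit).
#' @export
coarse_k_search <- function(spectrum, optics, prior_angle,
                            sector_halfwidth = 2.5, ring = c(0.5, 1.1)) {
  nr <- nrow(spectrum); nc <- ncol(spectrum)
  kc <- cutoff_frequency(optics)
  fg <- freq_grids(nr, nc)
  kr <- sqrt(fg$fy^2 + fg$fx^2)
  ang <- atan2(fg$fy, fg$fx) * 180 / pi
  mask <- kr >= ring[1] * kc & kr <= ring[2] * kc &
    abs(angle_diff(ang, prior_angle)) <= sector_halfwidth
  if (!any(mask))
    stop("empty coarse-search mask: check ring radii and prior sector")
  mag <- Mod(spectrum)
  mag[!mask] <- -Inf
  idx <- arrayInd(which.max(mag), dim(mag))
  k <- c(fg$fy[idx], fg$fx[idx])
  # flagged when the peak touches the mask edge (likely truncated optimum)
  nb <- rbind(idx + c(1, 0), idx - c(1, 0), idx + c(0, 1), idx - c(0, 1))
  nb[, 1] <- (nb[, 1] - 1) %% nr + 1; nb[, 2] <- (nb[, 2] - 1) %% nc + 1
  on_boundary <- !all(mask[nb])
  if (on_boundary)
    warning("coarse k peak lies on the search-mask boundary; ",
            "the true peak may sit outside the prior sector")
  structure(list(k = k, angle = atan2(k[1], k[2]) * 180 / pi,
                 magnitude = sqrt(sum(k^2)), peak_value = max(mag),
                 precision = "pixel", on_boundary = on_boundary,
                 n_search = sum(mask)), class = "k_vector")
}

#' Sub-pixel k-vector refinement and phase/modulation extraction
#'
#' Maximizes the magnitude of the overlap between the zero-order component
#' and the first-order component shifted by a candidate `k_theta` (the
#' shift applied as an exact spatial phase ramp), starting within a pixel
#' of the coarse estimate. At the optimum the complex overlap factor --
#' computed on the region where both OTF supports hold, with both OTFs
#' divided out -- has angle equal to the global illumination phase and
#' magnitude equal to the modulation depth `m`.
#'
#' @param components list with `order0` (zero-order reference spectrum) and
#'   `minus` (the first-order spectrum to align), e.g. from
#'   [separate_orders()] or the zero-order-free difference separation.
#' @param optics an [optics_model()].
#' @param k_init coarse `k_vector` (or numeric `c(ky, kx)`).
#' @param otf_floor OTF support threshold for the overlap region.
#' @param tol convergence tolerance on k (cycles/pixel).
#' @param max_iter optimizer iteration cap (0 = keep `k_init`, extract
#'   phase/modulation only).
#' @param side_scale amplitude of the side spectrum relative to
#'   `m exp(i phase)` times the true first order (1 for the full 3x3
#'   separation, 0.5 for the difference-separated side order).
#' @return list of class `illumination_estimate`: `k`, `angle`,
#'   `magnitude`, `subpixel` (FALSE when the optimizer failed, then `k`
#'   is the initial value), `global_phase` (radians), `modulation`,
#'   `modulation_flagged` (TRUE when m > 1.5 was clamped into range),
#'   `objective` (the final overlap ratio).
#' @export
refine_k_subpixel <- function(components, optics, k_init, otf_floor = 0.15,
                              tol = 1e-3, max_iter = 300L, side_scale = 1) {
  k0 <- if (inherits(k_init, "k_vector")) k_init$k else as.numeric(k_init)
  shp <- dim(components$order0)
  h <- otf_matrix(optics, shp)
  # overlap region fixed at the initial k; both OTFs divided out so the
  # correlation envelope is the sample autocorrelation, whose magnitude is
  # maximal exactly at zero lag (Cauchy-Schwarz) -- an unbiased optimum
  ov <- h > otf_floor & otf_matrix(optics, shp, k_off = k0) > otf_floor
  p0 <- components$order0[ov] / h[ov]
  sp_minus <- ifft2(components$minus)    # precomputed; one FFT per candidate
  cg <- coord_grids(shp[1], shp[2])
  shifted_at <- function(k) {
    fft2(sp_minus * exp(-2i * pi * (k[1] * cg$y + k[2] * cg$x)))
  }
  cross <- function(k) {
    hs <- otf_matrix(optics, shp, k_off = k)[ov]
    ps <- shifted_at(k)[ov] / hs
    abs(sum(ps * Conj(p0)))
  }
  if (max_iter > 0) {
    # parscale in frequency-bin units: the correlation peak is ~1 bin wide,
    # so the initial simplex must step a fraction of a bin
    fit <- stats::optim(k0, function(k) -cross(k), method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = max_iter,
                                       parscale = rep(1 / min(shp), 2)))
    converged <- fit$convergence == 0 &&
      sqrt(sum((fit$par - k0)^2)) <= 2 / min(shp)
    k <- if (converged) fit$par else k0
  } else {
    k <- k0          # fixed-k path: extract phase/modulation only
    converged <- TRUE
  }
  # overlap factor: regression of the shifted side order on the zero order
  # (OTFs divided out) equals m * exp(i * phase) in the noiseless model
  hs <- otf_matrix(optics, shp, k_off = k)[ov]
  ps <- shifted_at(k)[ov] / hs
  fac <- sum(ps * Conj(p0)) / sum(Mod(p0)^2)
  modulation <- Mod(fac) / side_scale
  flagged <- modulation > 1.5
  structure(list(k = k, angle = atan2(k[1], k[2]) * 180 / pi,
                 magnitude = sqrt(sum(k^2)),
                 subpixel = converged,
                 global_phase = Arg(fac),
                 overlap_factor = fac,
                 modulation = if (flagged) 1.5 else modulation,
                 modulation_flagged = flagged,
                 objective = Mod(sum(ps * Conj(p0))) / sum(Mod(ps)^2)),
            class = "illumination_estimate")
}

#' @export
print.illumination_estimate <- function(x, ...) {
  cat(sprintf("k = (%.4f, %.4f) c/px  |k| = %.4f  angle %.2f deg  %s\n",
              x$k[1], x$k[2], x$magnitude, x$angle,
              if (x$subpixel) "(sub-pixel)" else "(pixel, refinement failed)"))
  cat(sprintf("  global phase %.3f rad, modulation m = %.3f%s\n",
              x$global_phase, x$modulation,
              if (x$modulation_flagged) " [flagged > 1.5]" else ""))
  invisible(x)
}

#' Full illumination estimate for one angle
#'
#' Chains the estimation pipeline for one three-phase triplet: initial
#' phase differences by weighted cross-correlation minimization, a
#' zero-order-free side order from the difference separation,
#' prior-constrained coarse k search, sub-pixel k refinement, and a
#' closed-form phase refresh at the refined k (projections of the
#' difference spectra on the zero order give `u_j = g (e^{i phi_j} - 1)`
#' with `g = (m/2) e^{i phase}`; the ratio `u_2/u_1` yields both
#' differences independent of the initial estimate, and `g` then yields
#' the global phase and modulation depth). Refinement and refresh
#' alternate `n_refresh` times.
#'
#' @param images list of three preprocessed images (phases 1..3).
#' @param optics an [optics_model()].
#' @param prior_angle nominal pattern angle, degrees.
#' @param sector_halfwidth,ring coarse-search mask parameters.
#' @param refine_phases logical, Nelder-Mead polish of the initial phase
#'   differences.
#' @param fixed_k optional known k-vector: skip the coarse search and
#'   sub-pixel optimization, refresh phases/modulation only.
#' @param n_refresh alternations of k refinement and phase refresh.
#' @return list: `phase` (final `phi`, the initial estimate and search
#'   trace), `coarse` (`k_vector` or `NULL` when `fixed_k` given),
#'   `estimate` (`illumination_estimate`), `components` (separated orders
#'   at the final phases).
#' @export
estimate_illumination <- function(images, optics, prior_angle,
                                  sector_halfwidth = 2.5, ring = c(0.5, 1.1),
                                  refine_phases = TRUE, fixed_k = NULL,
                                  n_refresh = 2L) {
  stopifnot(length(images) == 3)
  d_fft <- lapply(images, fft2)
  shp <- dim(images[[1]])
  w <- build_weight(optics, shp)
  ph <- estimate_phase_differences(d_fft, w, refine = refine_phases)
  phi <- ph$phi
  diffs <- difference_spectra(d_fft)
  h <- otf_matrix(optics, shp)
  coarse <- NULL
  est <- NULL
  g <- NULL
  for (iter in seq_len(1L + n_refresh)) {
    comps <- separate_orders(d_fft, c(0, phi), m = 1)
    sepd <- separate_differences(diffs, phi)
    if (is.null(sepd))
      stop("degenerate phase differences: difference mixing matrix singular")
    side <- list(order0 = comps$order0, minus = sepd$A)
    if (iter == 1L) {
      if (is.null(fixed_k)) {
        coarse <- coarse_k_search(sepd$A, optics, prior_angle,
                                  sector_halfwidth = sector_halfwidth,
                                  ring = ring)
        k_cur <- coarse$k
      } else k_cur <- as.numeric(fixed_k)
    }
    est <- refine_k_subpixel(side, optics, k_cur, side_scale = 0.5,
                             max_iter = if (is.null(fixed_k)) 300L else 0L)
    k_cur <- est$k
    # closed-form phase refresh at the current k: projecting the
    # (zero-order-free) difference spectra on the zero order at +k gives
    # u_j = g (e^{i phi_j} - 1) with g = (m/2) e^{i phase}; the ratio
    # u_2/u_1 eliminates g, because e^{i phi} - 1 = 2i sin(phi/2) e^{i phi/2}:
    #   psi  = phi_3 - phi_2 = 2 Arg(u_2/u_1)
    #   tan(phi_2 / 2) = sin(psi/2) / (|u_2/u_1| - cos(psi/2))
    # making the refreshed differences independent of the initial estimate
    hs_p <- otf_matrix(optics, shp, k_off = k_cur)
    ov_p <- h > 0.15 & hs_p > 0.15
    p0p <- comps$order0[ov_p] / h[ov_p]
    np <- sum(Mod(p0p)^2)
    u <- vapply(1:2, function(j)
      sum((shift_spectrum(diffs[[j]], k_cur)[ov_p] / hs_p[ov_p]) * Conj(p0p)) / np,
      complex(1))
    if (Mod(u[1]) < 1e-12) break
    R <- u[2] / u[1]
    psi <- 2 * Arg(R)
    phi2 <- (2 * atan2(sin(psi / 2), Mod(R) - cos(psi / 2))) %% (2 * pi)
    phi3 <- (phi2 + psi) %% (2 * pi)
    if (!all(is.finite(c(phi2, phi3))) || min(phi2, phi3) < 1e-3) break
    phi <- c(phi2, phi3)
    g <- u[1] / (exp(1i * phi2) - 1)
    if (iter > n_refresh) break
  }
  comps <- separate_orders(d_fft, c(0, phi), m = 1)
  if (!is.null(g) && is.finite(Mod(g))) {
    est$global_phase <- Arg(g)
    est$overlap_factor <- g
    est$modulation <- min(2 * Mod(g), 1.5)
    est$modulation_flagged <- 2 * Mod(g) > 1.5
  }
  list(phase = list(phi = phi, objective = ph$objective,
                    initial_phi = ph$phi, trace = ph$trace),
       coarse = coarse, estimate = est, components = comps)
}
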