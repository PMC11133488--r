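# Acquisition-readout synchronization algebra for sub-ROI scanned SIM on a
# rolling-shutter sCMOS sensor.
#
# The six synchronization times (all in microseconds):
#   T_i   galvo dwell per sub-ROI position,
#   T_ii  SLM pattern switching duration (twice the nominal illumination
#         window, because the ferroelectric liquid crystal resets polarity),
#   T_iii SLM high-voltage duration,
#   T_D1  camera inter-frame exposure delay,
#   T_D2  delay between frame-exposure start and the scanner deflecting,
#   T_D3  per-step delay buffering the galvo settling (T_ii + T_D3 = T_i).

#' Acquisition timing plan
#'
#' Bundles the synchronization times, sensor line readout time and the
#' geometry of the opened sensor region into one validated object.
#'
#' @param t_i,t_ii,t_iii,t_d1,t_d2,t_d3 synchronization times, microseconds.
#' @param t_row sensor line readout time, microseconds (9.74 for the camera
#'   family the row budgets in [slm_presets()] assume).
#' @param n_subframes sub-ROIs exposed per opened sensor frame (6 for the
#'   2 x 3 layout).
#' @param n_patterns patterns per reconstruction group (6 or 9).
#' @param opened_rows opened sensor rows.
#' @param subroi_rows rows occupied by one sub-ROI (defaults to
#'   `opened_rows / 2`, the two-band layout).
#' @return object of class `timing_plan`.
#' @seealso [validate_plan()], [slm_presets()]
#' @export
timing_plan <- function(t_i, t_ii, t_iii, t_d1 = 0, t_d2 = 0, t_d3 = t_i - t_ii,
                        t_row = 9.74, n_subframes = 6L, n_patterns = 6L,
                        opened_rows = NULL, subroi_rows = NULL) {
  stopifnot(t_i >= 0, t_ii >= 0, t_iii >= 0, t_d1 >= 0, t_d2 >= 0,
            t_row > 0, n_subframes >= 1, n_patterns %in% c(6L, 9L))
  if (is.null(opened_rows))
    opened_rows <- min_opened_rows(t_ii, t_row, n_subframes)
  if (is.null(subroi_rows)) subroi_rows <- opened_rows / 2
  structure(list(t_i = t_i, t_ii = t_ii, t_iii = t_iii,
                 t_d1 = t_d1, t_d2 = t_d2, t_d3 = t_d3,
                 t_row = t_row, n_subframes = as.integer(n_subframes),
                 n_patterns = as.integer(n_patterns),
                 opened_rows = opened_rows, subroi_rows = subroi_rows),
            class = "timing_plan")
}

#' @export
print.timing_plan <- function(x, ...) {
  cat(sprintf("Timing plan (us): T_i %g  T_ii %g  T_iii %g  D1 %g  D2 %g  D3 %g\n",
              x$t_i, x$t_ii, x$t_iii, x$t_d1, x$t_d2, x$t_d3))
  cat(sprintf("  rows: opened %g (sub-ROI %g), line readout %g us, %d sub-frames\n",
              x$opened_rows, x$subroi_rows, x$t_row, x$n_subframes))
  cat(sprintf("  frame rate %d Hz (%d-pattern SIM rate %d Hz)\n",
              sim_framerate(x$t_d1, x$t_d2, x$t_i, x$n_subframes),
              x$n_patterns,
              sim_framerate(x$t_d1, x$t_d2, x$t_i, x$n_patterns)))
  v <- validate_plan(x)
  if (length(v)) cat("  VIOLATIONS:\n", paste0("   - ", v, "\n"), sep = "")
  invisible(x)
}

#' Minimum opened sensor rows for parallel sub-ROI exposure
#'
#' The opened region must hold `n_subframes` sub-ROIs whose staggered
#' exposure each spans the SLM switching duration, so it needs about
#' `n_subframes * t_ii / t_row` lines, rounded up to the sensor's row
#' granularity.
#'
#' @param t_ii SLM switching duration, microseconds.
#' @param t_row line readout time, microseconds.
#' @param n_subframes sub-ROIs per frame.
#' @param row_granularity sensor row-address granularity (rows are opened in
#'   multiples of this; 4 for the assumed camera family).
#' @return integer row count.
#' @examples
#' min_opened_rows(589, 9.74, 6)  # 364
#' @export
min_opened_rows <- function(t_ii, t_row, n_subframes, row_granularity = 4L) {
  stopifnot(t_ii > 0, t_row > 0, n_subframes > 0, row_granularity > 0)
  raw <- n_subframes * t_ii / t_row
  as.integer(ceiling(raw / row_granularity) * row_granularity)
}

#' Theoretical maximum raw sub-frame rate
#'
#' One pattern per SLM switching duration: `floor(1e6 / t_ii)` Hz.
#' @param t_ii SLM switching duration, microseconds.
#' @examples
#' max_raw_framerate(589)  # 1697
#' @export
max_raw_framerate <- function(t_ii) {
  stopifnot(t_ii > 0)
  as.integer(floor(1e6 / t_ii))
}

#' SIM frame rate from the synchronization times
#'
#' A reconstruction consumes `n_patterns` sub-ROIs; the whole-frame time is
#' `t_d1 + t_d2 + n_patterns * t_i` microseconds.
#'
#' @param t_d1,t_d2 frame delays, microseconds.
#' @param t_i galvo dwell per sub-ROI, microseconds.
#' @param n_patterns patterns per reconstruction (6 or 9).
#' @return integer Hz (floor).
#' @examples
#' sim_framerate(0, 0, 589, 6)  # 282
#' @export
sim_framerate <- function(t_d1, t_d2, t_i, n_patterns) {
  stopifnot(t_i > 0, n_patterns %in% c(6, 9))
  as.integer(floor(1e6 / (t_d1 + t_d2 + n_patterns * t_i)))
}

#' Validate a timing plan against the synchronization constraints
#'
#' Checks, reporting every violated rule with the offending numbers:
#' (a) `T_ii + T_D3 = T_i` within 1 us; (b) `T_ii <= T_i` (otherwise
#' patterns cross-talk between sub-ROIs or frames); (c) `T_iii <= T_ii`;
#' (d) the sub-ROI readout span covers half the pattern set,
#' `subroi_rows * t_row >= (n_subframes/2) * T_ii`; (e)
#' `opened_rows >= 2 * subroi_rows`.
#'
#' @param plan a [timing_plan()].
#' @return character vector of violations; empty when the plan is valid.
#' @export
validate_plan <- function(plan) {
  stopifnot(inherits(plan, "timing_plan"))
  v <- character()
  mismatch <- plan$t_ii + plan$t_d3 - plan$t_i
  if (abs(mismatch) > 1)
    v <- c(v, sprintf("T_ii + T_D3 != T_i: %g + %g = %g differs from %g by %g us",
                      plan$t_ii, plan$t_d3, plan$t_ii + plan$t_d3, plan$t_i,
                      mismatch))
  if (plan$t_ii > plan$t_i)
    v <- c(v, sprintf("crosstalk: T_ii (%g us) exceeds T_i (%g us)",
                      plan$t_ii, plan$t_i))
  if (plan$t_iii > plan$t_ii)
    v <- c(v, sprintf("T_iii (%g us) exceeds T_ii (%g us)", plan$t_iii, plan$t_ii))
  span <- plan$subroi_rows * plan$t_row
  need <- plan$n_subframes / 2 * plan$t_ii
  if (span < need - 1e-9)
    v <- c(v, sprintf("sub-ROI readout span %g us < (n/2) T_ii = %g us", span, need))
  if (plan$opened_rows < 2 * plan$subroi_rows)
    v <- c(v, sprintf("opened rows %g < 2 x sub-ROI rows %g",
                      plan$opened_rows, 2 * plan$subroi_rows))
  v
}

#' Spatio-temporal information flux
#'
#' `framerate * width * height / 1e6`, MPixels per second, one decimal.
#' @param framerate Hz.
#' @param width,height reconstructed pixels.
#' @examples
#' info_flux(256, 1352, 384)  # 132.9
#' @export
info_flux <- function(framerate, width, height) {
  stopifnot(framerate > 0, width > 0, height > 0)
  round(framerate * width * height / 1e6, 1)
}

#' Rolling-reconstruction cadence
#'
#' Advancing the sliding reconstruction window by `step` of the
#' `n_subframes` patterns multiplies the output rate by `n_subframes/step`.
#'
#' @param frame_time whole-frame time, milliseconds.
#' @param n_subframes patterns per frame.
#' @param step window advance (must divide `n_subframes`).
#' @return list with `interval` (ms) and `framerate` (Hz, 2 decimals).
#' @examples
#' rolling_cadence(4.9, 6, 3)  # 2.45 ms, 408.16 Hz
#' @export
rolling_cadence <- function(frame_time, n_subframes, step) {
  stopifnot(frame_time > 0, n_subframes > 0, step > 0)
  if (n_subframes %% step != 0)
    stop("step ", step, " does not divide the pattern-set size ", n_subframes)
  interval <- frame_time * step / n_subframes
  list(interval = interval, framerate = round(1000 / interval, 2))
}

#' Frames and raw sub-ROIs acquired in a given duration
#'
#' @param duration seconds.
#' @param frame_time whole-frame time, milliseconds.
#' @param n_subframes sub-ROIs per frame.
#' @return list with `frames` and `sub_rois` (integers).
#' @examples
#' acquisition_counts(10, 4.9, 6)  # 2040 frames, 12240 sub-ROIs
#' @export
acquisition_counts <- function(duration, frame_time, n_subframes) {
  stopifnot(duration >= 0, frame_time > 0, n_subframes > 0)
  frames <- as.integer(floor(duration * 1000 / frame_time))
  list(frames = frames, sub_rois = frames * as.integer(n_subframes))
}

#' Sub-ROI scan order on one sensor half
#'
#' The rolling shutter reads the sensor from the center outward, so the scan
#' must visit the 2 x 3 grid row nearest the sensor center first (left to
#' right), then the outer row. Top and bottom halves are vertical mirror
#' images. Positions are row-major indices 1..6 of the sub-ROI grid; the
#' returned vector gives, for patterns P1..P6 in pattern order, the grid
#' position each lands on.
#'
#' @param sensor_half `"top"` or `"bottom"`.
#' @return integer permutation of 1..6.
#' @export
scan_order <- function(sensor_half = c("top", "bottom")) {
  sensor_half <- match.arg(sensor_half)
  # grid row 2 is nearer the sensor center when the layout sits on the top half
  if (sensor_half == "top") c(4L, 5L, 6L, 1L, 2L, 3L) else c(1L, 2L, 3L, 4L, 5L, 6L)
}

#' Published SLM timing presets
#'
#' The advised synchronization times and row budgets for the two SLM series
#' at 0.2 ms and 0.4 ms pattern exposure (line readout 9.74 us), as one
#' data frame; `kind` distinguishes the advised operating plans
#' (`"advised"`, with dwell/delay times and occupied rows) from the
#' theoretical minimum-row entries (`"theoretical"`).
#'
#' @return data frame, one row per preset.
#' @export
slm_presets <- function() {
  rbind(
    data.frame(kind = "advised", slm = c("sxga", "sxga", "qxga", "qxga"),
               exposure_us = c(200, 400, 200, 400),
               t_ii = c(745, 945, 589, 789),
               t_i = c(795, 995, 649, 819),
               t_iii = c(370, 540, 210, 290),
               t_d1 = 0, t_d2 = 0,
               t_d3 = c(50, 50, 60, 30),
               rows = c(484, 608, 400, 496),
               framerate_hz = c(209, 167, 256, 204)),
    data.frame(kind = "theoretical", slm = c("sxga", "sxga", "qxga", "qxga"),
               exposure_us = c(200, 400, 200, 400),
               t_ii = c(745, 945, 589, 789),
               t_i = NA, t_iii = NA, t_d1 = 0, t_d2 = 0, t_d3 = NA,
               rows = c(460, 584, 364, 488),
               framerate_hz = c(1342, 1058, 1697, 1267))
  )
}

#' Timing plan for a published preset
#'
#' @param slm `"qxga"` or `"sxga"`.
#' @param exposure_us pattern exposure, 200 or 400 us.
#' @param kind `"advised"` (operating plan with dwell times) or
#'   `"theoretical"` (minimum-row plan, `t_i = t_ii`).
#' @param n_patterns patterns per reconstruction (6 or 9).
#' @return a [timing_plan()].
#' @examples
#' preset_plan("qxga", 200)
#' @export
preset_plan <- function(slm = c("qxga", "sxga"), exposure_us = 200,
                        kind = c("advised", "theoretical"), n_patterns = 6L) {
  slm <- match.arg(slm); kind <- match.arg(kind)
  tab <- slm_presets()
  row <- tab[tab$slm == slm & tab$exposure_us == exposure_us & tab$kind == kind, ]
  if (nrow(row) != 1) stop("no preset for ", slm, " at ", exposure_us, " us")
  if (kind == "advised") {
    timing_plan(row$t_i, row$t_ii, row$t_iii, row$t_d1, row$t_d2, row$t_d3,
                opened_rows = row$rows, n_patterns = n_patterns)
  } else {
    timing_plan(row$t_ii, row$t_ii, row$t_ii, 0, 0, 0,
                opened_rows = row$rows, n_patterns = n_patterns)
  }
}
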