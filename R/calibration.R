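#' Calibration ratio from a coordinate-paper image
#'
#' Estimates RA, the number of pixels covering one square millimetre, from an
#' image of the calibration grid. Grid lines are located as runs of
#' below-average intensity in the row and column mean-intensity profiles;
#' the mean spacing between consecutive line centres gives the pixel pitch of
#' one grid cell, and `ra = (pitch_px / grid_pitch_mm)^2`.
#'
#' When the pixel pitch is known by construction (fixed camera geometry),
#' supply it directly to the measurement functions via `ra` instead.
#'
#' @param grid_img A gray matrix showing a regular grid of known pitch.
#' @param grid_pitch_mm Physical spacing between grid lines in mm (default 1,
#'   the small squares of coordinate paper).
#' @return RA in pixels per mm^2 (scalar).
#' @export
calibrate <- function(grid_img, grid_pitch_mm = 1) {
  stopifnot(grid_pitch_mm > 0)
  spacing_px <- function(profile) {
    dev <- profile - mean(profile)
    s <- stats::sd(dev)
    if (!is.finite(s) || s == 0) return(NA_real_)
    hi <- dev > 0.5 * s
    lo <- dev < -0.5 * s
    # grid lines occupy the minority of the profile, whichever side they are
    mask <- if (any(hi) && (!any(lo) || sum(hi) <= sum(lo))) hi else lo
    if (!any(mask)) return(NA_real_)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    centers <- (starts[r$values] + ends[r$values]) / 2
    if (length(centers) < 2L) return(NA_real_)
    d <- diff(centers)
    med <- stats::median(d)
    # drop spurious centres (noise blobs) splitting or bridging a period
    d <- d[d > 0.6 * med & d < 1.7 * med]
    if (length(d) == 0L) return(NA_real_)
    mean(d)
  }
  sp <- c(spacing_px(rowMeans(grid_img)), spacing_px(colMeans(grid_img)))
  sp <- sp[is.finite(sp)]
  if (length(sp) == 0L) {
    stop("calibration grid not detected; supply `ra` directly", call. = FALSE)
  }
  (mean(sp) / grid_pitch_mm)^2
}

#' Convert pixel measurements to physical units
#'
#' Applies the calibration ratio RA (pixels per mm^2):
#' `length = pl / sqrt(ra)` mm, `mades = pw / sqrt(ra)` mm,
#' `pa = ppa / ra` mm^2 (also reported in cm^2, the unit used at the model
#' interface). An optional hair offset (mm) is subtracted from both linear
#' sizes to compensate the systematic oversize caused by surface hair being
#' segmented as fruit; it is 0 by default.
#'
#' @param pm A data frame with columns `pl`, `pw`, `ppa` (see
#'   [min_bounding_rect()]).
#' @param ra Calibration ratio in pixels per mm^2 (> 0).
#' @param weight_g Fruit weight(s) in grams, passed through.
#' @param hair_offset_mm Offset subtracted from `length_mm` and `mades_mm`.
#' @return A tibble with columns `weight_g`, `length_mm`, `mades_mm`,
#'   `pa_mm2`, `pa_cm2`.
#' @examples
#' pm <- tibble::tibble(pl = 330, pw = 270, ppa = 70000)
#' to_physical(pm, ra = 25, weight_g = 100)
#' @export
to_physical <- function(pm, ra, weight_g = NA_real_, hair_offset_mm = 0) {
  if (!is.numeric(ra) || any(ra <= 0)) stop("`ra` must be > 0", call. = FALSE)
  tibble::tibble(
    weight_g = weight_g,
    length_mm = pm$pl / sqrt(ra) - hair_offset_mm,
    mades_mm = pm$pw / sqrt(ra) - hair_offset_mm,
    pa_mm2 = pm$ppa / ra,
    pa_cm2 = pm$ppa / ra / 100
  )
}
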