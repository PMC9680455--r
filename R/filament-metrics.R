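#' Segment a suspended filament from a side-view image
#'
#' Red-dyed filaments image dark against a bright background, so the
#' default polarity treats low intensity as filament (`dark_foreground`);
#' RGB input (an H x W x 3 array) is reduced to a red-minus-green contrast
#' channel first, where the dyed filament is bright. Otsu thresholding is
#' followed by retention of the largest 8-connected component, which must
#' span at least half of the image width.
#'
#' @param image Integer matrix (grayscale) or H x W x 3 array (RGB).
#' @param calibration Pixels per mm.
#' @param dark_foreground Filament darker than background (grayscale path).
#' @param supports Optional `c(x_left, x_right)` pixel columns of the two
#'   supports; defaults to the component's horizontal extent.
#' @return A `filament_mask`: list with logical `mask`, `calibration`,
#'   `x_left`, `x_right`.
#' @export
segment_filament <- function(image, calibration, dark_foreground = TRUE,
                             supports = NULL) {
  if (length(dim(image)) == 3L) {
    # red-minus-green contrast: dye signal is positive
    d <- image[, , 1] - image[, , 2]
    img <- round(pmax(d, 0))
    dark_foreground <- FALSE
  } else {
    img <- round(image)
  }
  storage.mode(img) <- "integer"
  if (min(img) == max(img))
    stop("segment_filament: segmentation failure (image has no contrast)",
         call. = FALSE)
  thr <- otsu_threshold(img - min(img))
  fg <- if (dark_foreground) (img - min(img)) <= thr else (img - min(img)) > thr
  if (!any(fg))
    stop("segment_filament: segmentation failure (no foreground)",
         call. = FALSE)
  lab <- label_components(fg, 8L)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  cols <- which(colSums(comp) > 0)
  if (length(cols) < 0.5 * ncol(img))
    stop("segment_filament: segmentation failure (no component spanning >= 50% of width)",
         call. = FALSE)
  if (is.null(supports)) supports <- c(min(cols), max(cols))
  structure(list(mask = comp, calibration = calibration,
                 x_left = supports[1], x_right = supports[2]),
            class = "filament_mask")
}

# internal: midline row (centroid of mask pixels) for each column in span
filament_midline <- function(fm) {
  cols <- fm$x_left:fm$x_right
  y <- vapply(cols, function(cc) {
    r <- which(fm$mask[, cc])
    if (length(r) == 0) NA_real_ else mean(r)
  }, numeric(1))
  list(x = cols, y = y)
}

#' Measure deflection angles at the supports
#'
#' Fits a straight line to the filament midline over the first and last 10\%
#' of the span (at least 10 px) and reports the tangent angle from the
#' horizontal at each support, as positive magnitudes in degrees.
#'
#' @param fm A `filament_mask` from [segment_filament()].
#' @param window Fraction of the span used by each end fit.
#' @return Named numeric `c(theta1, theta2)` in degrees.
#' @export
measure_deflection_angles <- function(fm, window = 0.1) {
  stopifnot(inherits(fm, "filament_mask"))
  ml <- filament_midline(fm)
  ok <- !is.na(ml$y)
  x <- ml$x[ok]; y <- ml$y[ok]
  span <- length(x)
  w <- max(ceiling(window * span), 10L)
  if (span < 2 * w)
    stop("measure_deflection_angles: midline shorter than fit window",
         call. = FALSE)
  ang <- function(xs, ys) {
    slope <- stats::cov(xs, ys) / stats::var(xs)
    atan(abs(slope)) * 180 / pi
  }
  c(theta1 = ang(x[1:w], y[1:w]),
    theta2 = ang(x[(span - w + 1):span], y[(span - w + 1):span]))
}

#' Measure filament diameter at a span fraction
#'
#' Vertical mask extent at the requested column, corrected by the cosine of
#' the local midline slope to give the thickness perpendicular to the
#' filament axis, in mm.
#'
#' @param fm A `filament_mask`.
#' @param at Fraction of the span (0 = left support, 1 = right; default
#'   midspan).
#' @return Diameter in mm.
#' @export
measure_diameter <- function(fm, at = 0.5) {
  stopifnot(inherits(fm, "filament_mask"))
  if (at < 0 || at > 1)
    stop("measure_diameter: `at` must be within [0, 1]", call. = FALSE)
  col <- round(fm$x_left + at * (fm$x_right - fm$x_left))
  rows <- which(fm$mask[, col])
  if (length(rows) == 0)
    stop("measure_diameter: requested location is outside the mask",
         call. = FALSE)
  thickness_px <- length(rows)
  # local tangent from the midline around the location
  ml <- filament_midline(fm)
  sel <- which(abs(ml$x - col) <= 5 & !is.na(ml$y))
  slope <- if (length(sel) >= 3) {
    stats::cov(ml$x[sel], ml$y[sel]) / stats::var(ml$x[sel])
  } else 0
  thickness_px * cos(atan(slope)) / fm$calibration
}

#' Time for the deflection angles to flatten
#'
#' First crossing of each angle below `angle_threshold`, located by linear
#' interpolation between the bracketing frames. Angles that never flatten
#' are reported as the `NA` not-reached sentinel. Input times are seconds;
#' results are minutes, matching how collapse times are usually quoted.
#'
#' @param series Data frame with columns `t` (s, sorted increasing),
#'   `theta1`, `theta2` (deg).
#' @param angle_threshold Flatness threshold in degrees (default 0.5; an
#'   exact 0 is unattainable under pixel quantisation).
#' @return Named numeric `c(t1_flat, t2_flat)` in minutes.
#' @export
time_to_flat <- function(series, angle_threshold = 0.5) {
  if (nrow(series) < 2) stop("time_to_flat: need >= 2 frames", call. = FALSE)
  if (is.unsorted(series$t, strictly = FALSE))
    stop("time_to_flat: series must be sorted by t", call. = FALSE)
  crossing <- function(ang) {
    below <- which(ang <= angle_threshold)
    if (length(below) == 0) return(NA_real_)
    i <- below[1]
    t_cross <- if (i == 1) {
      series$t[1]
    } else {
      series$t[i - 1] + (ang[i - 1] - angle_threshold) /
        (ang[i - 1] - ang[i]) * (series$t[i] - series$t[i - 1])
    }
    t_cross / 60
  }
  c(t1_flat = crossing(series$theta1), t2_flat = crossing(series$theta2))
}

#' Diameter-shrink slope
#'
#' Magnitude of the OLS slope of diameter (mm) against time (min).
#' Evaporative shrinkage is reported as a positive number, so faster drying
#' gives a larger slope.
#'
#' @param series Data frame with columns `t` (s) and `diameter` (mm).
#' @return Slope in mm/min (positive magnitude).
#' @export
diameter_slope <- function(series) {
  if (nrow(series) < 2)
    stop("diameter_slope: need >= 2 frames", call. = FALSE)
  t_min <- series$t / 60
  abs(stats::cov(t_min, series$diameter) / stats::var(t_min))
}

#' Summarise a deflection time series
#'
#' @param series Data frame with `t` (s), `theta1`, `theta2` (deg),
#'   `diameter` (mm).
#' @param angle_threshold Flatness threshold (deg).
#' @return List with `time_to_flat_theta1`, `time_to_flat_theta2` (min),
#'   `diameter_slope` (mm/min), `n_frames`, `angle_threshold`.
#' @export
summarize_series <- function(series, angle_threshold = 0.5) {
  tf <- time_to_flat(series, angle_threshold)
  list(time_to_flat_theta1 = unname(tf["t1_flat"]),
       time_to_flat_theta2 = unname(tf["t2_flat"]),
       diameter_slope = diameter_slope(series),
       n_frames = nrow(series),
       angle_threshold = angle_threshold)
}
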