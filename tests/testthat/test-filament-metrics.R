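# Fixture frames rendered from the beam model carry analytic truth (sag,
# support tangent angle, radius), so extraction accuracy is checked against
# ground truth that was never measured from the image.

render_default <- function(E = 1e4, kL = 1, gap_mm = 8, r_mm = 0.4, ...) {
  p <- default_beam(E = E, L = gap_mm * 1e-3, r = r_mm * 1e-3, kL = kL)
  render_filament_frame(p, r_mm = r_mm, calibration = 45, ...)
}

test_that("segmentation recovers the rendered filament", {
  fr <- render_default()
  fm <- segment_filament(fr$image, 45,
                         supports = c(fr$truth$x_left_px, fr$truth$x_right_px))
  expect_s3_class(fm, "filament_mask")
  # ground-truth mask: pixels clearly dark in the noise-free rendering
  truth_mask <- fr$image < 128
  inter <- sum(fm$mask & truth_mask)
  union <- sum(fm$mask | truth_mask)
  expect_gt(inter / union, 0.95)
  # blank image fails
  expect_error(segment_filament(matrix(200L, 50, 200), 45), "failure")
  # inverted contrast with polarity flag gives the same mask
  inv <- 255L - fr$image
  fm2 <- segment_filament(inv, 45, dark_foreground = FALSE,
                          supports = c(fr$truth$x_left_px, fr$truth$x_right_px))
  expect_equal(fm2$mask, fm$mask)
})

test_that("deflection angles match the analytic support tangents within 1 degree", {
  for (kL in c(0.5, 1)) {
    fr <- render_default(kL = kL)
    fm <- segment_filament(fr$image, 45,
                           supports = c(fr$truth$x_left_px,
                                        fr$truth$x_right_px))
    ang <- measure_deflection_angles(fm)
    expect_lt(abs(ang["theta1"] - fr$truth$theta_deg), 1)
    expect_lt(abs(ang["theta2"] - fr$truth$theta_deg), 1)
  }
  # horizontal filament reads (0, 0)
  stiff <- render_default(E = 1e7)
  fms <- segment_filament(stiff$image, 45,
                          supports = c(stiff$truth$x_left_px,
                                       stiff$truth$x_right_px))
  a0 <- measure_deflection_angles(fms)
  expect_lt(a0["theta1"], 0.2)
  expect_lt(a0["theta2"], 0.2)
})

test_that("metrics are invariant under horizontal mirroring up to angle swap", {
  fr <- render_default()
  W <- ncol(fr$image)
  fm <- segment_filament(fr$image, 45,
                         supports = c(fr$truth$x_left_px, fr$truth$x_right_px))
  fm_m <- segment_filament(fr$image[, W:1], 45,
                           supports = c(W - fr$truth$x_right_px + 1,
                                        W - fr$truth$x_left_px + 1))
  a <- measure_deflection_angles(fm)
  am <- measure_deflection_angles(fm_m)
  expect_equal(unname(a["theta1"]), unname(am["theta2"]), tolerance = 1e-8)
  expect_equal(unname(a["theta2"]), unname(am["theta1"]), tolerance = 1e-8)
  expect_equal(measure_diameter(fm), measure_diameter(fm_m),
               tolerance = 1e-8)
})

test_that("diameter measurement is calibrated and tolerant of upsampling", {
  fr <- render_default()
  fm <- segment_filament(fr$image, 45,
                         supports = c(fr$truth$x_left_px, fr$truth$x_right_px))
  d <- measure_diameter(fm)
  expect_lt(abs(d - 0.8), 1 / 45)      # within one pixel equivalent
  # rendering at doubled calibration leaves the mm diameter unchanged
  p <- default_beam()
  fr2 <- render_filament_frame(p, r_mm = 0.4, calibration = 90)
  fm2 <- segment_filament(fr2$image, 90,
                          supports = c(fr2$truth$x_left_px,
                                       fr2$truth$x_right_px))
  expect_lt(abs(measure_diameter(fm2) - d), 1 / 45)
  # tapered fixture: thicker at quarter span than at midspan
  rvec <- seq(0.5, 0.3, length.out = ncol(fr$image))
  frt <- render_filament_frame(p, r_mm = rvec, calibration = 45)
  fmt <- segment_filament(frt$image, 45,
                          supports = c(frt$truth$x_left_px,
                                       frt$truth$x_right_px))
  expect_gt(measure_diameter(fmt, 0.25), measure_diameter(fmt, 0.5))
  expect_error(measure_diameter(fmt, 1.4), "\\[0, 1\\]")
})

test_that("time_to_flat interpolates the first crossing", {
  # theta1 linear 20 -> 0 deg over 6 min
  s <- data.frame(t = seq(0, 360, by = 60),
                  theta1 = seq(20, 0, length.out = 7),
                  theta2 = seq(10, 0, length.out = 7) * 0)
  tf <- time_to_flat(s, angle_threshold = 0.5)
  expect_equal(unname(tf["t1_flat"]), 6 * (1 - 0.5 / 20))
  expect_equal(unname(tf["t2_flat"]), 0)   # already flat at t = 0
  # never flat: NA sentinel
  s2 <- data.frame(t = c(0, 60), theta1 = c(20, 10), theta2 = c(5, 4))
  expect_true(is.na(time_to_flat(s2)["t1_flat"]))
  # unsorted input rejected
  s3 <- s; s3$t <- rev(s3$t)
  expect_error(time_to_flat(s3), "sorted")
  # monotone: uniformly faster decay never flattens later
  fast <- data.frame(t = s$t, theta1 = s$theta1 * 0.5, theta2 = s$theta2)
  expect_lte(time_to_flat(fast)["t1_flat"], tf["t1_flat"])
})

test_that("diameter slope is the positive OLS magnitude in mm/min", {
  # 1.0 -> 0.72 mm over 10 min, linear: 0.028 mm/min shrink
  s <- data.frame(t = seq(0, 600, by = 60),
                  diameter = seq(1.0, 0.72, length.out = 11))
  expect_equal(diameter_slope(s), 0.028, tolerance = 1e-12)
  expect_equal(diameter_slope(data.frame(t = c(0, 60, 120),
                                         diameter = c(1, 1, 1))), 0)
  # hand OLS on 3 points
  s3 <- data.frame(t = c(0, 60, 120), diameter = c(1.0, 0.9, 0.85))
  tm <- s3$t / 60
  beta <- sum((tm - mean(tm)) * (s3$diameter - mean(s3$diameter))) /
    sum((tm - mean(tm))^2)
  expect_equal(diameter_slope(s3), abs(beta))
  expect_error(diameter_slope(s3[1, ]), ">= 2")
})

test_that("series summary distinguishes fast from slow drying regimes", {
  mk <- function(rate) {
    t <- seq(0, 600, by = 60)
    data.frame(t = t, theta1 = pmax(20 - rate * 200 * t / 60, 0),
               theta2 = pmax(15 - rate * 200 * t / 60, 0),
               diameter = 1 - rate * t / 60)
  }
  fast <- summarize_series(mk(0.028))   # incubator-style
  slow <- summarize_series(mk(0.012))   # room-temperature-style
  expect_gt(fast$diameter_slope, slow$diameter_slope)
  expect_lt(fast$time_to_flat_theta1, slow$time_to_flat_theta1)
  expect_equal(fast$n_frames, 11)
})
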