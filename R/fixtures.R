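# Seed-scoped RNG: evaluates expr with a local, restorable random state so
# generators are deterministic without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

# Add an axis-aligned rectangle [x0,x1] x [y0,y1] (mm) to an intensity image
# with anti-aliased (area-coverage) edges. `origin_mm` maps pixel (1,1)'s
# top-left corner to mm coordinates; mode "max" draws, "erase" clears.
add_rect_mm <- function(img, x0, x1, y0, y1, cal, origin_mm = c(0, 0),
                        value = 255, mode = c("max", "erase")) {
  mode <- match.arg(mode)
  H <- nrow(img); W <- ncol(img)
  cov_axis <- function(a, b, n, orig) {
    lo <- (seq_len(n) - 1) / cal + orig
    hi <- lo + 1 / cal
    pmin(hi, b) - pmax(lo, a)
  }
  cx <- pmax(cov_axis(x0, x1, W, origin_mm[1]) * cal, 0)
  cy <- pmax(cov_axis(y0, y1, H, origin_mm[2]) * cal, 0)
  cover <- outer(cy, cx)
  if (mode == "max") {
    pmax(img, value * cover)
  } else {
    img[cover > 0] <- 0
    img
  }
}

#' Render a synthetic grid-scaffold image with controlled defects
#'
#' Draws the designed lattice (bright material on dark background) at the
#' spec's calibration and applies an exact, analytically known defect set:
#' `merge` removes the wall between two adjacent cells, `fill` closes one
#' cell, and `spread_fraction > 1` widens every line (emulating a
#' low-viscosity ink spreading; wide enough lines close all pores). The
#' ground truth is computed from the geometry, never from the rendering.
#'
#' @param spec A [grid_spec()].
#' @param defects List of defects, each `list(type = "merge", a = c(r, c),
#'   b = c(r, c))` for adjacent cells or `list(type = "fill",
#'   cell = c(r, c))`.
#' @param spread_fraction Line-width multiplier (`>= 1`).
#' @param noise_sigma Additive Gaussian pixel noise (intensity units).
#' @param margin_mm Background margin around the design.
#' @param seed RNG seed for the noise.
#' @return List with `image` (integer matrix) and `truth` (a pore-record
#'   data frame in the same shape as [match_pores_to_grid()] output).
#' @export
make_grid_image <- function(spec, defects = list(), spread_fraction = 1,
                            noise_sigma = 0, margin_mm = 1, seed = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spread_fraction < 1)
    stop("make_grid_image: spread_fraction must be >= 1", call. = FALSE)
  n <- spec$cells_per_side
  pitch <- spec$pitch
  lw <- spec$line_width * spread_fraction
  cal <- spec$calibration
  # validate defects
  filled <- list(); merges <- list()
  for (d in defects) {
    if (identical(d$type, "fill")) {
      filled <- c(filled, list(d$cell))
    } else if (identical(d$type, "merge")) {
      if (sum(abs(d$a - d$b)) != 1L)
        stop("make_grid_image: merge cells must be lattice-adjacent",
             call. = FALSE)
      merges <- c(merges, list(d))
    } else stop("make_grid_image: unknown defect type", call. = FALSE)
  }
  key <- function(rc) paste(rc[1], rc[2])
  fill_keys <- vapply(filled, key, character(1))
  merge_keys <- unlist(lapply(merges, function(d) c(key(d$a), key(d$b))))
  if (length(intersect(fill_keys, merge_keys)))
    stop("make_grid_image: contradictory defects (fill + merge on one cell)",
         call. = FALSE)
  ext <- spec$span + lw + 2 * margin_mm     # rendered extent in mm
  Wpx <- ceiling(ext * cal); Hpx <- ceiling(ext * cal)
  img <- matrix(0, Hpx, Wpx)
  origin <- c(-(lw / 2 + margin_mm), -(lw / 2 + margin_mm))
  lo <- -lw / 2; hi <- spec$span + lw / 2
  for (k in 0:n) {
    x0 <- k * pitch
    img <- add_rect_mm(img, x0 - lw / 2, x0 + lw / 2, lo, hi, cal, origin)
    img <- add_rect_mm(img, lo, hi, x0 - lw / 2, x0 + lw / 2, cal, origin)
  }
  open_w <- pitch - lw                       # analytic open-cell edge
  pores_open <- open_w > 0.05 * pitch        # spread ink can close them
  for (d in merges) {
    rc <- if (d$a[2] != d$b[2]) {            # horizontal neighbours
      c2 <- max(d$a[2], d$b[2]) - 1L
      r <- d$a[1]
      list(x0 = c2 * pitch - lw / 2, x1 = c2 * pitch + lw / 2,
           y0 = (r - 1) * pitch + lw / 2, y1 = r * pitch - lw / 2)
    } else {                                 # vertical neighbours
      r2 <- max(d$a[1], d$b[1]) - 1L
      c0 <- d$a[2]
      list(x0 = (c0 - 1) * pitch + lw / 2, x1 = c0 * pitch - lw / 2,
           y0 = r2 * pitch - lw / 2, y1 = r2 * pitch + lw / 2)
    }
    img <- add_rect_mm(img, rc$x0, rc$x1, rc$y0, rc$y1, cal, origin,
                       mode = "erase")
  }
  for (cell in filled) {
    img <- add_rect_mm(img,
                       (cell[2] - 1) * pitch + lw / 2, cell[2] * pitch - lw / 2,
                       (cell[1] - 1) * pitch + lw / 2, cell[1] * pitch - lw / 2,
                       cal, origin)
  }
  img <- with_seed(seed, {
    if (noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sigma)
    img
  })
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  # analytic truth
  truth <- data.frame(cell_row = rep(seq_len(n), each = n),
                      cell_col = rep(seq_len(n), times = n),
                      pore_id = NA_integer_,
                      centroid_x_mm = rep((seq_len(n) - 0.5) * pitch, times = n),
                      centroid_y_mm = rep((seq_len(n) - 0.5) * pitch, each = n),
                      area_mm2 = if (pores_open) open_w^2 else 0,
                      status = if (pores_open) "ok" else "filled",
                      stringsAsFactors = FALSE)
  # note centroid columns above: x varies along cell_col (times), y along rows
  truth$centroid_x_mm <- (truth$cell_col - 0.5) * pitch
  truth$centroid_y_mm <- (truth$cell_row - 0.5) * pitch
  if (pores_open) {
    for (d in merges) {
      for (rc in list(d$a, d$b)) {
        i <- which(truth$cell_row == rc[1] & truth$cell_col == rc[2])
        truth$status[i] <- "merged"
        truth$area_mm2[i] <- 2 * open_w^2 + lw * open_w
      }
    }
    for (cell in filled) {
      i <- which(truth$cell_row == cell[1] & truth$cell_col == cell[2])
      truth$status[i] <- "filled"
      truth$area_mm2[i] <- 0
    }
  }
  list(image = img, truth = truth)
}

# analytic support-tangent slope of the dispatched beam solution
beam_support_slope <- function(params) {
  sol <- beam_solution(params)
  if (sol$q == 0) return(0)
  if (sol$mode == "classic_limit") {
    sol$q * sol$L^3 / (24 * sol$EI)
  } else {
    m <- sol$k * sol$L / 2
    (sol$q / sol$P) * (sol$L / 2 - tanh(m) / sol$k)
  }
}

#' Render one side-view filament frame
#'
#' The filament midline follows the beam deflection profile between the two
#' supports (and rests level on the support margins); the stroke is drawn
#' with the thickness perpendicular to the midline equal to the local
#' diameter, with area-coverage anti-aliasing, dark ink on a bright
#' background.
#'
#' @param params A [beam_parameters()] (SI units).
#' @param r_mm Filament radius in mm: a scalar, or a vector over the span's
#'   pixel columns for tapered test fixtures.
#' @param calibration Pixels per mm.
#' @param margin_mm Support margin on each side.
#' @param noise_sigma Additive Gaussian pixel noise.
#' @param seed RNG seed for the noise.
#' @param fg,bg Filament and background intensities.
#' @return List with `image` and `truth` (`w_max_mm`, `theta_deg`,
#'   analytic midspan sag and support tangent angle).
#' @export
render_filament_frame <- function(params, r_mm, calibration = 45,
                                  margin_mm = 1, noise_sigma = 0, seed = NULL,
                                  fg = 25, bg = 230) {
  stopifnot(inherits(params, "beam_parameters"))
  gap_mm <- params$L * 1000
  sol <- beam_solution(params)
  w_max_mm <- deflection_profile(sol, params$L / 2) * 1000
  theta_deg <- atan(beam_support_slope(params)) * 180 / pi
  Wpx <- ceiling((gap_mm + 2 * margin_mm) * calibration)
  r_max <- max(r_mm)
  Hpx <- ceiling((w_max_mm + 2 * r_max + 2 * margin_mm) * calibration)
  x_mm <- (seq_len(Wpx) - 0.5) / calibration - margin_mm   # 0 at left support
  y0_mm <- margin_mm + r_max                               # rest midline
  in_span <- x_mm >= 0 & x_mm <= gap_mm
  w_mm <- numeric(Wpx)
  w_mm[in_span] <- deflection_profile(sol, x_mm[in_span] / 1000) * 1000
  mid_row <- (y0_mm + w_mm) * calibration                  # in pixel units
  r_col <- rep_len(r_mm, Wpx)
  # local slope for perpendicular-thickness correction
  slope <- c(0, diff(mid_row)) / 1           # px per px
  half <- r_col * calibration / cos(atan(slope))
  rows <- seq_len(Hpx)
  img <- matrix(bg, Hpx, Wpx)
  for (j in seq_len(Wpx)) {
    lo <- mid_row[j] - half[j]; hi <- mid_row[j] + half[j]
    cover <- pmin(rows, hi) - pmax(rows - 1, lo)
    cover <- pmin(pmax(cover, 0), 1)
    img[, j] <- bg + (fg - bg) * cover
  }
  img <- with_seed(seed, {
    if (noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sigma)
    img
  })
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  supports_px <- c(ceiling(margin_mm * calibration),
                   floor((margin_mm + gap_mm) * calibration))
  list(image = img,
       truth = list(w_max_mm = w_max_mm, theta_deg = theta_deg,
                    r_mm = if (length(r_mm) == 1) r_mm else NA_real_,
                    gap_mm = gap_mm, x_left_px = supports_px[1],
                    x_right_px = supports_px[2]))
}

#' Generate a ground-truthed filament collapse image series
#'
#' Emulates the filament collapse test: a filament of initial radius
#' `r0_mm` suspended across each requested gap, its radius shrinking
#' linearly with time as water evaporates (faster at incubator temperature
#' than at room temperature), re-solved quasi-statically at every frame.
#' Per-frame truth (radius, analytic midspan sag, support tangent angle) is
#' recorded analytically, never measured from the rendering.
#'
#' @param E_true Young's modulus of the ink (Pa).
#' @param P Transfer loading / axial tension (N).
#' @param r0_mm Initial filament radius (mm).
#' @param shrink_rate Radius shrink rate (mm/min).
#' @param rho Density (kg/m^3).
#' @param gaps Support gaps (mm).
#' @param frame_interval Seconds between frames.
#' @param n_frames Frames per gap.
#' @param calibration Pixels per mm.
#' @param noise_sigma Additive Gaussian pixel noise.
#' @param seed RNG seed (noise only; geometry is deterministic).
#' @return List keyed by gap (`"gap_4"` etc.), each with `frames` (list of
#'   integer matrices) and `truth` (data frame `t_s`, `r_mm`, `w_max_mm`,
#'   `theta1_deg`, `theta2_deg`, `diameter_mm`, `gap_mm`, `E_true`).
#' @export
make_filament_series <- function(E_true, P, r0_mm = 0.4, shrink_rate = 0.014,
                                 rho = 1026, gaps = c(1, 2, 4, 8, 16),
                                 frame_interval = 60, n_frames = 10,
                                 calibration = 45, noise_sigma = 0,
                                 seed = NULL) {
  duration_min <- (n_frames - 1) * frame_interval / 60
  if (r0_mm - shrink_rate * duration_min <= 0)
    stop("make_filament_series: radius would reach zero within the series",
         call. = FALSE)
  out <- list()
  for (gi in seq_along(gaps)) {
    gap <- gaps[gi]
    frames <- vector("list", n_frames)
    truth <- data.frame(t_s = (seq_len(n_frames) - 1) * frame_interval)
    truth$r_mm <- r0_mm - shrink_rate * truth$t_s / 60
    truth$w_max_mm <- NA_real_
    truth$theta1_deg <- NA_real_
    for (i in seq_len(n_frames)) {
      p <- beam_parameters(E = E_true, P = P, r = truth$r_mm[i] / 1000,
                           rho = rho, L = gap / 1000)
      fr <- render_filament_frame(
        p, r_mm = truth$r_mm[i], calibration = calibration,
        noise_sigma = noise_sigma,
        seed = if (is.null(seed)) NULL else seed + 1000L * gi + i)
      frames[[i]] <- fr$image
      truth$w_max_mm[i] <- fr$truth$w_max_mm
      truth$theta1_deg[i] <- fr$truth$theta_deg
    }
    truth$theta2_deg <- truth$theta1_deg    # uniform load is symmetric
    truth$diameter_mm <- 2 * truth$r_mm
    truth$gap_mm <- gap
    truth$E_true <- E_true
    out[[paste0("gap_", gap)]] <- list(frames = frames, truth = truth)
  }
  out
}

#' Generate a ground-truthed two-channel fluorescence z-stack
#'
#' Places `n_live` green and `n_dead` red Gaussian spots by rejection
#' sampling with a per-channel minimum separation, assigns each spot a
#' focal plane (full amplitude there, defocus-attenuated on neighbouring
#' planes so the max projection recovers the full amplitude), and adds
#' pixel noise.
#'
#' @param n_live,n_dead Spot counts for the green (Calcein/live) and red
#'   (EthD/dead) channels.
#' @param width,height Image size (px).
#' @param spot_sigma Gaussian spot radius (px).
#' @param amplitude Peak spot intensity.
#' @param min_separation Minimum centre-to-centre spacing within a channel
#'   (px).
#' @param n_planes Number of focal planes.
#' @param z_range_um Axial range (um).
#' @param noise_sigma Pixel noise scale.
#' @param noise `"gaussian"` (additive) or `"poisson"`.
#' @param seed RNG seed; fixes placement and noise.
#' @return List with `stack` (a [z_stack()]) and `truth` (`live_count`,
#'   `dead_count`, `positions` data frame).
#' @export
make_zstack <- function(n_live, n_dead, width = 256, height = 256,
                        spot_sigma = 2, amplitude = 200, min_separation = 12,
                        n_planes = 6, z_range_um = 100, noise_sigma = 4,
                        noise = c("gaussian", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  margin <- ceiling(3 * spot_sigma) + 1
  if (width - 2 * margin < 1 || height - 2 * margin < 1)
    stop("make_zstack: image too small for the requested spots", call. = FALSE)
  with_seed(seed, {
    place <- function(n_spots) {
      xs <- numeric(0); ys <- numeric(0)
      attempts <- 0L
      while (length(xs) < n_spots) {
        attempts <- attempts + 1L
        if (attempts > 200L * max(n_spots, 1L))
          stop("make_zstack: could not place spots at min_separation ",
               "(image too crowded)", call. = FALSE)
        x <- stats::runif(1, margin, width - margin)
        y <- stats::runif(1, margin, height - margin)
        if (length(xs) == 0 ||
            min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
          xs <- c(xs, x); ys <- c(ys, y)
        }
      }
      list(x = xs, y = ys,
           plane = if (n_spots > 0)
             sample.int(n_planes, n_spots, replace = TRUE) else integer(0))
    }
    spots <- list(green = place(n_live), red = place(n_dead))
    a <- array(0, c(n_planes, 2, height, width))
    win <- ceiling(4 * spot_sigma)
    for (ch in 1:2) {
      s <- spots[[ch]]
      for (i in seq_along(s$x)) {
        cx <- s$x[i]; cy <- s$y[i]
        c0 <- max(1, floor(cx) - win); c1 <- min(width, ceiling(cx) + win)
        r0 <- max(1, floor(cy) - win); r1 <- min(height, ceiling(cy) + win)
        dx2 <- ((c0:c1) - cx)^2
        dy2 <- ((r0:r1) - cy)^2
        blob <- amplitude * exp(-outer(dy2, dx2, "+") / (2 * spot_sigma^2))
        for (p in seq_len(n_planes)) {
          att <- exp(-(p - s$plane[i])^2 / 2)   # defocus attenuation
          a[p, ch, r0:r1, c0:c1] <- a[p, ch, r0:r1, c0:c1] + att * blob
        }
      }
    }
    if (noise_sigma > 0) {
      if (noise == "gaussian") {
        a <- a + stats::rnorm(length(a), 0, noise_sigma)
      } else {
        a <- array(stats::rpois(length(a), lambda = a + noise_sigma),
                   dim(a))
      }
    }
    a <- round(pmin(pmax(a, 0), 255))
    storage.mode(a) <- "integer"
    mk_pos <- function(name, s) {
      data.frame(channel = rep(name, length(s$x)), x = s$x, y = s$y,
                 plane = s$plane)
    }
    positions <- rbind(mk_pos("green", spots$green), mk_pos("red", spots$red))
    list(stack = z_stack(a, z_range_um = z_range_um),
         truth = list(live_count = n_live, dead_count = n_dead,
                      positions = positions))
  })
}
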