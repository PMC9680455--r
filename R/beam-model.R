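#' Geometry and material state of one suspended filament segment
#'
#' Bundles the parameters of the tensioned simply-supported beam model of a
#' hanging bioink filament: a cylindrical filament of radius `r` and density
#' `rho` spanning a gap `L` between two supports, loaded transversely by its
#' own weight and axially by a "transfer loading" `P` (the tension exerted by
#' adjacent material). Section properties are derived on construction:
#' second moment of area `I = pi r^4 / 4`, cross-section `A = pi r^2`, and
#' distributed load `q = rho * g * A` (N/m, positive in the sag direction).
#'
#' @param E Young's modulus (Pa).
#' @param P Axial tension / transfer loading (N). Must be `>= 0`.
#' @param r Filament radius (m). Must satisfy `r < L`.
#' @param rho Bioink density (kg/m^3); about 1026 for a 4\% alginate ink.
#' @param L Gap length between supports (m).
#' @param g Gravitational acceleration (m/s^2).
#'
#' @return An object of class `beam_parameters`: a list with the inputs plus
#'   derived `I`, `A` and `q`.
#' @examples
#' p <- beam_parameters(E = 1e4, P = 1e-6, r = 4e-4, rho = 1026, L = 4e-3)
#' p$q  # self-weight line load in N/m
#' @export
beam_parameters <- function(E, P, r, rho, L, g = 9.81) {
  for (nm in c("E", "r", "rho", "L", "g")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("beam_parameters: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0) {
    stop("beam_parameters: `P` must be a single non-negative number",
         call. = FALSE)
  }
  if (r >= L) {
    stop("beam_parameters: slender-filament assumption requires r < L",
         call. = FALSE)
  }
  obj <- list(E = E, P = P, r = r, rho = rho, L = L, g = g)
  sec <- derive_section_properties(obj)
  obj$I <- sec$I
  obj$A <- sec$A
  obj$q <- sec$q
  structure(obj, class = "beam_parameters")
}

#' Section properties of a cylindrical filament
#'
#' @param params A `beam_parameters` object, or any list with positive
#'   numeric fields `r`, `rho`, `g`.
#' @return List with `I` (m^4), `A` (m^2) and `q` (N/m): the cylinder's
#'   second moment of area `pi r^4/4`, cross-section `pi r^2`, and
#'   self-weight line load `rho * g * A`.
#' @export
derive_section_properties <- function(params) {
  r <- params$r; rho <- params$rho; g <- params$g
  if (is.null(g)) g <- 9.81
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 ||
      !is.numeric(rho) || rho <= 0 || !is.numeric(g) || g <= 0) {
    stop("derive_section_properties: r, rho and g must be positive",
         call. = FALSE)
  }
  A <- pi * r^2
  list(I = pi * r^4 / 4, A = A, q = rho * g * A)
}

# Threshold on the dimensionless tension k*L below which the high-level
# dispatcher switches to the classic (untensioned) closed form.
.kl_switch <- 1e-2

#' Closed-form solution of the tensioned simply-supported beam
#'
#' Solves `w'''' - (P/EI) w'' = q/EI` with simply-supported boundary
#' conditions `w(0) = w(L) = 0`, `w''(0) = w''(L) = 0`. The general solution
#' is `w(x) = c1 + c2 x + c3 exp(kx) + c4 exp(-kx) - q x^2 / (2P)` with
#' `k = sqrt(P/(EI))`. Internally the exponential pair is carried in a
#' cosh/sinh basis centred at `L/2`, which is symmetric and immune to
#' `exp(kL)` overflow; `c3`/`c4` are recovered by back-transformation (they
#' may be non-finite for very large `kL` even though profile evaluation
#' remains stable).
#'
#' @param params A `beam_parameters` object with `P > 0`.
#' @return A `beam_solution` object with fields `c1..c4`, `k`, `q`, `P`,
#'   `EI`, `L` and `mode = "closed_form_tensioned"`.
#' @seealso [classic_limit_deflection()] for the `P -> 0` limit,
#'   [beam_solution()] for the dispatching constructor.
#' @export
solve_coefficients <- function(params) {
  stopifnot(inherits(params, "beam_parameters"))
  if (params$P <= 0) {
    stop(structure(
      class = c("beam_tension_zero", "error", "condition"),
      list(message = paste0(
             "solve_coefficients: P = 0 has no tensioned closed form; ",
             "use classic_limit_deflection()"),
           call = sys.call())))
  }
  EI <- params$E * params$I
  k <- sqrt(params$P / EI)
  q <- params$q
  P <- params$P
  L <- params$L
  m <- k * L / 2
  # C * cosh(k u) with C = q / (P k^2 cosh(m)); u = x - L/2
  c1 <- -q / (P * k^2)
  c2 <- q * L / (2 * P)
  Ccoef <- q / (P * k^2 * cosh(m))
  structure(
    list(c1 = c1, c2 = c2,
         c3 = Ccoef * exp(-m) / 2, c4 = Ccoef * exp(m) / 2,
         k = k, q = q, P = P, EI = EI, L = L,
         mode = "closed_form_tensioned"),
    class = "beam_solution")
}

#' Beam solution dispatcher
#'
#' Returns the tensioned closed form when the dimensionless tension
#' `kL = sqrt(P/EI) * L` is at least `1e-2`, and otherwise (including
#' `P = 0`) the classic untensioned limit, whose midspan deflection is
#' `5qL^4/(384EI)`. The switch avoids the `-q x^2/(2P)` degeneracy of the
#' tensioned form as `P -> 0`; at the switch point the two branches agree to
#' a few parts in 1e5.
#'
#' @inheritParams solve_coefficients
#' @return A `beam_solution` with `mode` either `"closed_form_tensioned"` or
#'   `"classic_limit"`.
#' @export
beam_solution <- function(params) {
  stopifnot(inherits(params, "beam_parameters"))
  EI <- params$E * params$I
  kL <- if (params$P > 0) sqrt(params$P / EI) * params$L else 0
  if (kL < .kl_switch) {
    structure(
      list(c1 = NA_real_, c2 = NA_real_, c3 = NA_real_, c4 = NA_real_,
           k = kL / params$L, q = params$q, P = params$P, EI = EI,
           L = params$L, mode = "classic_limit"),
      class = "beam_solution")
  } else {
    solve_coefficients(params)
  }
}

#' Evaluate a beam deflection profile
#'
#' Sag-positive convention: `w >= 0` under positive load, maximal at
#' `x = L/2`.
#'
#' @param sol A `beam_solution`.
#' @param x Position(s) along the span, in `[0, L]` (m).
#' @return Deflection `w(x)` in metres (vectorised over `x`).
#' @export
deflection_profile <- function(sol, x) {
  stopifnot(inherits(sol, "beam_solution"))
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > sol$L * (1 + 1e-12))) {
    stop("deflection_profile: x must lie within [0, L]", call. = FALSE)
  }
  x <- pmin(pmax(x, 0), sol$L)
  L <- sol$L
  q <- sol$q
  if (q == 0) return(rep(0, length(x)))
  if (sol$mode == "classic_limit") {
    # classic simply-supported uniform-load quartic
    return(q * x * (L^3 - 2 * L * x^2 + x^3) / (24 * sol$EI))
  }
  k <- sol$k
  P <- sol$P
  u <- x - L / 2
  m <- k * L / 2
  if (m < 1) {
    # cancellation-free form for small tension: with v = k u,
    # w = q/(P k^2) * [h(v) - h(m) + (m^2 - v^2)/2 * (cosh m - 1)] / cosh m
    # where h(t) = cosh t - 1 - t^2/2 (series-expanded near 0)
    h_fn <- function(t) {
      out <- numeric(length(t))
      small <- t < 0.1
      ts <- t[small]
      out[small] <- ts^4 / 24 + ts^6 / 720 + ts^8 / 40320
      out[!small] <- cosh(t[!small]) - 1 - t[!small]^2 / 2
      out
    }
    v <- k * abs(u)
    coshm1 <- 2 * sinh(m / 2)^2
    w <- (q / (P * k^2)) *
      (h_fn(v) - h_fn(m) + (m^2 - v^2) / 2 * coshm1) / cosh(m)
  } else {
    # 1 - cosh(ku)/cosh(m) computed without overflow via scaled exponentials
    a <- k * abs(u)
    ratio <- exp(a - m) * (1 + exp(-2 * a)) / (1 + exp(-2 * m))
    w <- (q / P) * (L^2 / 8 - u^2 / 2 - (1 - ratio) / k^2)
  }
  pmax(w, 0)
}

#' Midspan deflection of the classic (untensioned) simply-supported beam
#'
#' Numerically stable `P -> 0` limit: `w_max = 5 q L^4 / (384 EI)`.
#'
#' @inheritParams solve_coefficients
#' @return Maximum (midspan) deflection in metres.
#' @export
classic_limit_deflection <- function(params) {
  stopifnot(inherits(params, "beam_parameters"))
  5 * params$q * params$L^4 / (384 * params$E * params$I)
}

#' Midspan deflection under the dispatched solution
#'
#' @inheritParams solve_coefficients
#' @return `w(L/2)` in metres.
#' @export
beam_midpoint_deflection <- function(params) {
  sol <- beam_solution(params)
  deflection_profile(sol, params$L / 2)
}

#' Finite-difference solution of the tensioned beam boundary-value problem
#'
#' Independent numerical oracle for the closed form (standing in for
#' solid-model FEA at desk scale): second-order central differences for
#' `w'''' - (P/EI) w'' = q/EI` on a uniform grid, with `w = w'' = 0` at both
#' supports imposed through reflected ghost nodes. Error decreases as
#' `h^2`.
#'
#' @inheritParams solve_coefficients
#' @param n_nodes Number of grid nodes including both supports (`>= 16`).
#' @return Numeric vector of length `n_nodes`: the deflection profile at
#'   `seq(0, L, length.out = n_nodes)`, with attribute `x` holding the grid.
#' @export
solve_deflection_numeric <- function(params, n_nodes = 257) {
  stopifnot(inherits(params, "beam_parameters"))
  if (n_nodes < 16) stop("solve_deflection_numeric: n_nodes must be >= 16",
                         call. = FALSE)
  EI <- params$E * params$I
  L <- params$L
  n <- n_nodes - 1L          # intervals
  h <- L / n
  ni <- n - 1L               # interior unknowns
  alpha <- params$P / EI * h^2   # tension term scaled by h^2
  # rows: (w[i-2] - 4w[i-1] + 6w[i] - 4w[i+1] + w[i+2])
  #       - alpha (w[i-1] - 2w[i] + w[i+1]) = q h^4 / EI
  Amat <- matrix(0, ni, ni)
  for (i in seq_len(ni)) {
    if (i - 2 >= 1) Amat[i, i - 2] <- 1
    if (i - 1 >= 1) Amat[i, i - 1] <- -4 - alpha
    Amat[i, i] <- 6 + 2 * alpha
    if (i + 1 <= ni) Amat[i, i + 1] <- -4 - alpha
    if (i + 2 <= ni) Amat[i, i + 2] <- 1
  }
  # ghost reflection w[-1] = -w[1], w[n+1] = -w[n-1] (from w'' = 0, w = 0)
  Amat[1, 1] <- Amat[1, 1] - 1
  Amat[ni, ni] <- Amat[ni, ni] - 1
  rhs <- rep(params$q * h^4 / EI, ni)
  w_int <- tryCatch(solve(Amat, rhs), error = function(e) {
    stop("solve_deflection_numeric: singular discretization (degenerate parameters)",
         call. = FALSE)
  })
  w <- c(0, w_int, 0)
  attr(w, "x") <- seq(0, L, length.out = n_nodes)
  w
}

#' Estimate Young's modulus from an observed midspan deflection
#'
#' Inverts the forward model `w_max(E)` (which is strictly decreasing in
#' `E`, so the root is unique) by bisection on `log10(E)` to a relative
#' tolerance of 1e-6, within a bracket spanning soft hydrogels by default.
#'
#' @param w_obs Observed midspan deflection (m), `> 0`.
#' @param params `beam_parameters` supplying everything except `E` (its `E`
#'   field is ignored).
#' @param bracket Length-2 numeric, `[E_lo, E_hi]` in Pa.
#' @param t Optional time stamp (s) carried through to the result.
#' @return A `modulus_estimate` object: list with `t`, `E_hat` (Pa), `r`
#'   (m) and `w_obs` (m).
#' @export
estimate_modulus <- function(w_obs, params, bracket = c(10, 1e7), t = NA_real_) {
  stopifnot(inherits(params, "beam_parameters"))
  if (!is.numeric(w_obs) || length(w_obs) != 1L || !is.finite(w_obs) || w_obs <= 0)
    stop("estimate_modulus: w_obs must be a single positive number", call. = FALSE)
  if (length(bracket) != 2L || any(bracket <= 0) || bracket[1] >= bracket[2])
    stop("estimate_modulus: bracket must be increasing and positive", call. = FALSE)
  fwd <- function(E) {
    p <- params
    p$E <- E
    beam_midpoint_deflection(p)
  }
  w_lo <- fwd(bracket[1])   # softest -> largest sag
  w_hi <- fwd(bracket[2])
  if (w_obs > w_lo || w_obs < w_hi) {
    stop(sprintf(paste0(
      "estimate_modulus: w_obs = %.4g m outside the achievable range ",
      "[%.4g, %.4g] m for bracket [%.3g, %.3g] Pa"),
      w_obs, w_hi, w_lo, bracket[1], bracket[2]), call. = FALSE)
  }
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  if (w_obs == w_lo) {
    E_hat <- bracket[1]
  } else if (w_obs == w_hi) {
    E_hat <- bracket[2]
  } else {
    for (it in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (fwd(10^mid) > w_obs) lo <- mid else hi <- mid
      if (10^hi - 10^lo <= 1e-6 * 10^lo) break
    }
    E_hat <- 10^((lo + hi) / 2)
  }
  structure(list(t = t, E_hat = E_hat, r = params$r, w_obs = w_obs),
            class = "modulus_estimate")
}

# Tangent-fit angle (deg) the angle-measurement operator would report for an
# analytic profile: OLS slope of w over the leading `window` fraction of the
# span, evaluated at `n_pts` sample points. Mirrors measure_deflection_angles.
model_support_angle <- function(params, window = 0.1, n_pts = 50L) {
  sol <- beam_solution(params)
  xs <- seq(0, params$L * window, length.out = n_pts)
  ws <- deflection_profile(sol, xs)
  slope <- stats::cov(xs, ws) / stats::var(xs)
  atan(abs(slope)) * 180 / pi
}

#' Estimate Young's modulus from measured support angles
#'
#' Measurement-consistent inversion for the image pipeline: the same
#' windowed tangent-fit operator that [measure_deflection_angles()] applies
#' to a segmented filament is applied to the model profile, and the modulus
#' is found (bisection on `log10 E`) such that the model's support angle
#' matches the mean of the two observed angles. The chord-derived midspan
#' deflection [angles_to_midpoint_deflection()] is recorded as `w_obs`
#' metadata but is not the quantity inverted, because the straight-chord
#' approximation over-estimates the true midspan sag of the curved profile.
#'
#' @param theta1,theta2 Observed deflection angles at the supports (deg).
#' @param params `beam_parameters` supplying everything except `E`.
#' @param bracket `[E_lo, E_hi]` in Pa.
#' @param window Fraction of the span used by the tangent fit (matches the
#'   measurement operator).
#' @param t Optional time stamp (s).
#' @return A `modulus_estimate` object.
#' @export
estimate_modulus_from_angles <- function(theta1, theta2, params,
                                         bracket = c(10, 1e7),
                                         window = 0.1, t = NA_real_) {
  stopifnot(inherits(params, "beam_parameters"))
  th <- (theta1 + theta2) / 2
  if (!is.finite(th) || th <= 0 || th >= 90)
    stop("estimate_modulus_from_angles: mean angle must be in (0, 90) degrees",
         call. = FALSE)
  fwd <- function(E) {
    p <- params
    p$E <- E
    model_support_angle(p, window = window)
  }
  a_lo <- fwd(bracket[1]); a_hi <- fwd(bracket[2])
  if (th > a_lo || th < a_hi) {
    stop(sprintf(paste0(
      "estimate_modulus_from_angles: angle %.3g deg outside achievable ",
      "range [%.3g, %.3g] deg for bracket [%.3g, %.3g] Pa"),
      th, a_hi, a_lo, bracket[1], bracket[2]), call. = FALSE)
  }
  lo <- log10(bracket[1]); hi <- log10(bracket[2])
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (fwd(10^mid) > th) lo <- mid else hi <- mid
    if (10^hi - 10^lo <= 1e-6 * 10^lo) break
  }
  E_hat <- 10^((lo + hi) / 2)
  w_obs <- angles_to_midpoint_deflection(theta1, theta2, params$L)
  structure(list(t = t, E_hat = E_hat, r = params$r, w_obs = w_obs),
            class = "modulus_estimate")
}

#' Linear regression of Young's modulus against filament radius
#'
#' Ordinary least squares `E = slope * r + intercept`; as the filament dries
#' and thins, the modulus rises, so the fitted slope on drying series is
#' negative.
#'
#' @param r Radii (m).
#' @param E_hat Estimated moduli (Pa), same length as `r`.
#' @return A `modulus_radius_fit` object: list with `slope` (Pa/m),
#'   `intercept` (Pa), `r_squared` and `n_points`.
#' @export
fit_modulus_vs_radius <- function(r, E_hat) {
  if (length(r) != length(E_hat) || length(r) < 2)
    stop("fit_modulus_vs_radius: need >= 2 (r, E) points", call. = FALSE)
  if (length(unique(r)) < 2)
    stop("fit_modulus_vs_radius: degenerate fit, all radii identical",
         call. = FALSE)
  fit <- stats::lm(E_hat ~ r)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((E_hat - mean(E_hat))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = min(max(r2, 0), 1),
                 n_points = length(r)),
            class = "modulus_radius_fit")
}

#' Chord approximation of midspan deflection from support angles
#'
#' Straight-chord conversion `w_max = (L/2) * tan((theta1 + theta2)/2)`,
#' both angles measured from the horizontal at the supports.
#'
#' @param theta1,theta2 Deflection angles (deg), in `[0, 90)`.
#' @param L Span (m, or any length unit; the result shares it).
#' @return Midspan deflection estimate in the unit of `L`.
#' @export
angles_to_midpoint_deflection <- function(theta1, theta2, L) {
  if (any(c(theta1, theta2) < 0) || any(c(theta1, theta2) >= 90))
    stop("angles_to_midpoint_deflection: angles must be in [0, 90) degrees",
         call. = FALSE)
  (L / 2) * tanpi(((theta1 + theta2) / 2) / 180)
}
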