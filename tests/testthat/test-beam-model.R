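test_that("section properties follow the cylinder formulas", {
  # constants chosen so q collapses to 1 N/m
  p <- beam_parameters(E = 1, P = 0, r = 1, rho = 1 / (pi * 9.81), L = 2)
  expect_equal(p$q, 1, tolerance = 1e-12)
  expect_equal(p$I, pi / 4)
  expect_equal(p$A, pi)

  # 4% alginate filament at the nominal radius; independent arithmetic:
  # q = 1026 * 9.81 * pi * (4e-4)^2 = 5.0597e-3 N/m
  p2 <- beam_parameters(E = 1e4, P = 0, r = 4e-4, rho = 1026, L = 4e-3)
  expect_equal(p2$q, 5.0597e-3, tolerance = 1e-4)
  expect_equal(p2$I, pi * (4e-4)^4 / 4)

  # power laws: doubling r multiplies I by 16 and q by 4
  p3 <- beam_parameters(E = 1e4, P = 0, r = 8e-4, rho = 1026, L = 4e-3)
  expect_equal(p3$I / p2$I, 16)
  expect_equal(p3$q / p2$q, 4)

  expect_error(beam_parameters(E = 1e4, P = 0, r = -1e-4, rho = 1026,
                               L = 4e-3), "positive")
  expect_error(beam_parameters(E = 1e4, P = 0, r = 5e-3, rho = 1026,
                               L = 4e-3), "r < L")
  expect_error(derive_section_properties(list(r = 1e-4, rho = -1, g = 9.81)),
               "positive")
})

test_that("closed-form solution satisfies the boundary conditions", {
  p <- default_beam()
  sol <- solve_coefficients(p)
  expect_identical(sol$mode, "closed_form_tensioned")
  w_max <- deflection_profile(sol, p$L / 2)
  expect_lt(abs(deflection_profile(sol, 0)), 1e-9 * max(1, w_max))
  expect_lt(abs(deflection_profile(sol, p$L)), 1e-9 * max(1, w_max))
  # w''(0) = w''(L) = 0 via second differences of the profile
  h <- p$L * 1e-4
  d2 <- function(x0) {
    xs <- pmin(pmax(c(x0, x0 + h, x0 + 2 * h), 0), p$L)
    ws <- deflection_profile(sol, xs)
    (ws[1] - 2 * ws[2] + ws[3]) / h^2
  }
  expect_lt(abs(d2(0)), 1e-4 * max(1, abs(sol$q / sol$P)))
  # Eq.-(8) coefficient form reproduces the profile at interior points
  xs <- seq(0.1, 0.9, by = 0.2) * p$L
  w_coef <- sol$c1 + sol$c2 * xs + sol$c3 * exp(sol$k * xs) +
    sol$c4 * exp(-sol$k * xs) - sol$q / (2 * sol$P) * xs^2
  expect_equal(w_coef, deflection_profile(sol, xs), tolerance = 1e-9)
  # P = 0 signals the classic limit
  p0 <- beam_parameters(E = 1e4, P = 0, r = 4e-4, rho = 1026, L = 8e-3)
  expect_error(solve_coefficients(p0), class = "beam_tension_zero")
  expect_identical(beam_solution(p0)$mode, "classic_limit")
})

test_that("massless filament does not deflect", {
  p <- default_beam()
  p$q <- 0
  sol <- structure(list(c1 = 0, c2 = 0, c3 = 0, c4 = 0, k = 1, q = 0,
                        P = p$P, EI = p$E * p$I, L = p$L,
                        mode = "closed_form_tensioned"),
                   class = "beam_solution")
  expect_equal(deflection_profile(sol, seq(0, p$L, length.out = 7)),
               rep(0, 7))
  expect_equal(max(abs(solve_deflection_numeric(p, 64))), 0)
})

test_that("profile is symmetric with its maximum at midspan", {
  p <- default_beam()
  sol <- solve_coefficients(p)
  xs <- seq(0, p$L, length.out = 10001)
  ws <- deflection_profile(sol, xs)
  expect_equal(xs[which.max(ws)], p$L / 2, tolerance = 1e-4)
  expect_equal(ws, rev(ws), tolerance = 1e-9)
  expect_equal(deflection_profile(sol, 0.3 * p$L),
               deflection_profile(sol, 0.7 * p$L), tolerance = 1e-9)
  expect_true(all(ws >= 0))
  expect_error(deflection_profile(sol, -0.1 * p$L), "within")
  expect_error(deflection_profile(sol, 1.1 * p$L), "within")
})

test_that("closed form matches the finite-difference oracle over a random sweep", {
  set.seed(42)
  for (i in 1:20) {
    E <- 10^stats::runif(1, 2.5, 5)
    r <- stats::runif(1, 2e-4, 6e-4)
    L <- sample(c(2, 4, 8, 16), 1) * 1e-3
    kL <- 10^stats::runif(1, -1, 1)
    I <- pi * r^4 / 4
    p <- beam_parameters(E = E, P = kL^2 * E * I / L^2, r = r, rho = 1026,
                         L = L)
    w_cf <- beam_midpoint_deflection(p)
    w_fd <- max(solve_deflection_numeric(p, 1025))
    expect_lt(abs(w_cf - w_fd) / w_cf, 1e-4)
  }
})

test_that("finite-difference solver converges at second order", {
  p <- default_beam(kL = 2)
  w_exact <- beam_midpoint_deflection(p)
  err <- function(n) abs(max(solve_deflection_numeric(p, n)) - w_exact)
  e1 <- err(65); e2 <- err(129); e3 <- err(257)
  expect_gt(e1 / e2, 3)
  expect_gt(e2 / e3, 3)
  expect_error(solve_deflection_numeric(p, 8), ">= 16")
})

test_that("tensioned solution converges to the classic limit as P -> 0", {
  p <- default_beam()
  # rebuild with kL = 1e-3
  P_small <- (1e-3)^2 * p$E * p$I / p$L^2
  ps <- beam_parameters(E = p$E, P = P_small, r = p$r, rho = p$rho, L = p$L)
  sol <- solve_coefficients(ps)
  w_t <- deflection_profile(sol, ps$L / 2)
  w_c <- classic_limit_deflection(ps)
  expect_lt(abs(w_t - w_c) / w_c, 1e-3)
  # classic limit basics: q = 0 gives 0; doubling E halves w
  p2 <- beam_parameters(E = 2 * p$E, P = p$P, r = p$r, rho = p$rho, L = p$L)
  expect_equal(classic_limit_deflection(p2),
               classic_limit_deflection(p) / 2)
})

test_that("midspan deflection is monotone in E, L and q", {
  base <- default_beam()
  w_of <- function(E = base$E, L = base$L, rho = base$rho) {
    beam_midpoint_deflection(
      beam_parameters(E = E, P = base$P, r = base$r, rho = rho, L = L))
  }
  Es <- 10^seq(3, 5, length.out = 10)
  expect_true(all(diff(vapply(Es, function(E) w_of(E = E), 1)) < 0))
  Ls <- seq(2e-3, 16e-3, length.out = 10)
  expect_true(all(diff(vapply(Ls, function(L) w_of(L = L), 1)) > 0))
  rhos <- seq(500, 2000, length.out = 10)   # q is proportional to rho
  expect_true(all(diff(vapply(rhos, function(rh) w_of(rho = rh), 1)) > 0))
})

test_that("modulus estimation inverts the forward model", {
  p <- default_beam()
  for (E_star in c(1e3, 1e4, 1e5)) {
    pp <- beam_parameters(E = E_star, P = p$P, r = p$r, rho = p$rho, L = p$L)
    w <- beam_midpoint_deflection(pp)
    est <- estimate_modulus(w, p)
    expect_s3_class(est, "modulus_estimate")
    expect_lt(abs(est$E_hat - E_star) / E_star, 1e-3)
  }
  # boundary root: w at E_lo returns E_lo
  bracket <- c(1e3, 1e6)
  p_lo <- beam_parameters(E = bracket[1], P = p$P, r = p$r, rho = p$rho,
                          L = p$L)
  w_lo <- beam_midpoint_deflection(p_lo)
  expect_equal(estimate_modulus(w_lo, p, bracket)$E_hat, bracket[1])
  # monotonicity: larger sag, smaller modulus
  e1 <- estimate_modulus(w_lo / 2, p, bracket)
  e2 <- estimate_modulus(w_lo / 4, p, bracket)
  expect_gt(e2$E_hat, e1$E_hat)
  # out-of-range observation reports the achievable interval
  expect_error(estimate_modulus(w_lo * 10, p, bracket), "achievable")
})

test_that("modulus-radius regression matches the normal equations", {
  # exact line
  r <- c(3e-4, 4e-4, 5e-4)
  E <- 2e7 * r + 100
  fit <- fit_modulus_vs_radius(r, E)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2e7, tolerance = 1e-6)
  expect_equal(fit$intercept, 100, tolerance = 1e-6)
  # hand-computed OLS on 3 noisy points
  r2 <- c(1, 2, 4); E2 <- c(5, 4, 1)
  sxx <- sum((r2 - mean(r2))^2)
  sxy <- sum((r2 - mean(r2)) * (E2 - mean(E2)))
  f2 <- fit_modulus_vs_radius(r2, E2)
  expect_equal(f2$slope, sxy / sxx)
  expect_equal(f2$intercept, mean(E2) - sxy / sxx * mean(r2))
  expect_true(f2$r_squared >= 0 && f2$r_squared <= 1)
  # drying series: E rises as r falls, so the slope is negative
  expect_lt(f2$slope, 0)
  expect_error(fit_modulus_vs_radius(c(1, 1), c(2, 3)), "degenerate")
  # noise consistency: sigma -> 0 recovers the generating line
  set.seed(9)
  rr <- seq(2e-4, 6e-4, length.out = 20)
  EE <- -3e7 * rr + 2e4 + stats::rnorm(20, 0, 1e-3)
  f3 <- fit_modulus_vs_radius(rr, EE)
  expect_equal(f3$slope, -3e7, tolerance = 1e-4)
  expect_equal(f3$intercept, 2e4, tolerance = 1e-4)
})

test_that("angle-to-deflection chord conversion", {
  expect_equal(angles_to_midpoint_deflection(0, 0, 8), 0)
  expect_equal(angles_to_midpoint_deflection(45, 45, 8), 4)
  expect_equal(angles_to_midpoint_deflection(30, 0, 8), 4 * tan(15 * pi / 180))
  expect_error(angles_to_midpoint_deflection(95, 0, 8), "90")
  expect_error(angles_to_midpoint_deflection(-2, 0, 8), "90")
})

test_that("angle-based inversion recovers the modulus it forward-simulates", {
  p <- default_beam()
  for (E_star in c(2e3, 2e4)) {
    pp <- beam_parameters(E = E_star, P = p$P, r = p$r, rho = p$rho, L = p$L)
    th <- bioprintfidelity:::model_support_angle(pp)
    est <- estimate_modulus_from_angles(th, th, p)
    expect_lt(abs(est$E_hat - E_star) / E_star, 1e-4)
  }
})
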