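test_that("characteristic roots solve the boundary eigenvalue equation", {
  # beta = 0 reduces to the zeros of J0
  r0 <- characteristic_roots(0, 3)
  expect_equal(r0$alpha, c(2.404825557695773, 5.520078110286311,
                           8.653727912911013), tolerance = 1e-12)
  # anchor-set beta: first root sits below the first J0 zero
  r <- characteristic_roots(0.2042, 20)
  expect_lt(r$alpha[1], 2.40483)
  expect_equal(r$alpha[1], 2.315, tolerance = 1e-3)
  # against the independent bisection oracle
  expect_equal(r$alpha[1:10], bisect_char_roots(0.2042, 10), tolerance = 1e-8)
  # residual of the characteristic equation below 1e-12
  resid <- abs(r$alpha * besselJ(r$alpha, 0) - r$beta * besselJ(r$alpha, 1))
  expect_lt(max(resid), 1e-12)
  expect_true(all(diff(r$alpha) > 0))
})

test_that("every root decreases as beta increases", {
  betas <- c(0, 0.1, 0.3, 0.6, 0.9)
  all_roots <- sapply(betas, function(b) characteristic_roots(b, 8)$alpha)
  for (n in 1:8) expect_true(all(diff(all_roots[n, ]) < 0))
})

test_that("invalid beta is rejected", {
  expect_error(characteristic_roots(-0.1, 5), "beta")
  expect_error(characteristic_roots(1, 5), "beta")
  expect_error(characteristic_roots(0.5, 0), "n_roots")
})

test_that("step response carries the correct limiting moduli", {
  set <- anchor_50()
  C <- stiffness_from_engineering(set$ec)
  roots <- characteristic_roots(1 - C$C12 / C$C11, 20)
  sol <- step_response(C, roots, tg = set$tp$tg)
  expect_equal(sol$E3_eq, 19.19, tolerance = 1e-10)
  expect_equal(sol$M0, 24.9571, tolerance = 1e-4)
  expect_equal(sol$M0, C$C33 - 2 * C$C13 + (C$C11 + C$C12) / 2,
               tolerance = 1e-12)
  expect_true(all(diff(sol$tau) < 0))
  # amplitudes sum toward M0 - E3; convergence is ~1/alpha^2, so 20 roots
  # capture ~98% and ~400 roots reach the 0.1% level
  frac20 <- sum(sol$B) / (sol$M0 - sol$E3_eq)
  expect_gt(frac20, 0.97)
  sol400 <- step_response(C, characteristic_roots(roots$beta, 400), set$tp$tg)
  expect_equal(sum(sol400$B), sol400$M0 - sol400$E3_eq, tolerance = 1e-3)
  # mismatched root set is refused
  wrong <- characteristic_roots(0.5, 20)
  expect_error(step_response(C, wrong, set$tp$tg), "beta")
})

test_that("isotropic step peak-to-equilibrium ratio is 3/(2(1+nu))", {
  for (nu in c(0.15, 0.3, 0.45)) {
    C <- stiffness_from_engineering(engineering_constants(10, 10, nu, nu))
    roots <- characteristic_roots(1 - C$C12 / C$C11, 5)
    sol <- step_response(C, roots)
    expect_equal(sol$M0 / sol$E3_eq, 3 / (2 * (1 + nu)), tolerance = 1e-6)
  }
  # nu = 0 gives beta = 1 (outside the characteristic-root domain) but the
  # moduli ratio itself still has the closed-form limit 3/2
  C0 <- stiffness_from_engineering(engineering_constants(10, 10, 0, 0))
  M0 <- C0$C33 - 2 * C0$C13 + (C0$C11 + C0$C12) / 2
  E3 <- C0$C33 - 2 * C0$C13^2 / (C0$C11 + C0$C12)
  expect_equal(M0 / E3, 1.5, tolerance = 1e-12)
})

test_that("load intensity honors equilibrium, step and superposition limits", {
  set <- anchor_50()
  C <- stiffness_from_engineering(set$ec)
  beta <- 1 - C$C12 / C$C11
  sol <- step_response(C, characteristic_roots(beta, 20), set$tp$tg)

  # equilibrium: P(infinity) = E3 * eps0
  pr <- ramp_protocol(0.01, 0.1, 100)
  P_inf <- load_intensity(sol, pr, 12 * set$tp$tg)$stress_kPa
  expect_equal(P_inf, 1.919, tolerance = 1e-4)

  # step P(0+) converges to M0 * eps0 with a large root set
  solL <- step_response(C, characteristic_roots(beta, 2000), set$tp$tg)
  step_pr <- ramp_protocol(Inf, 0.1)
  P0 <- load_intensity(solL, step_pr, 0)$stress_kPa
  expect_equal(P0, 2.496, tolerance = 2e-3)

  # finite-rate peak bounded by the step peak; trace continuous at t0,
  # monotone decreasing during the hold
  times <- seq(0, 110, by = 0.01)
  tr <- load_intensity(sol, pr, times)
  expect_lt(max(tr$stress_kPa), sol$M0 * 0.1)
  i0 <- which.min(abs(times - pr$ramp_time))
  expect_lt(abs(tr$stress_kPa[i0 + 1] - tr$stress_kPa[i0]), 5e-3)
  hold <- tr$stress_kPa[times > pr$ramp_time]
  expect_true(all(diff(hold) < 0))

  expect_error(load_intensity(sol, pr, numeric(0)), "empty")
  expect_error(load_intensity(sol, pr, c(-1, 0)), "non-negative")
})

test_that("time axis rescales with tg when the protocol rescales too", {
  set <- anchor_50()
  C <- stiffness_from_engineering(set$ec)
  roots <- characteristic_roots(1 - C$C12 / C$C11, 20)
  c_fac <- 3.7
  sol1 <- step_response(C, roots, tg = 10)
  sol2 <- step_response(C, roots, tg = 10 * c_fac)
  pr1 <- ramp_protocol(0.01, 0.1)
  pr2 <- ramp_protocol(0.01 / c_fac, 0.1)
  t1 <- seq(0, 60, by = 0.5)
  P1 <- load_intensity(sol1, pr1, t1)$stress_kPa
  P2 <- load_intensity(sol2, pr2, t1 * c_fac)$stress_kPa
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("radial fields satisfy boundary and equilibrium constraints", {
  set <- anchor_50()
  C <- stiffness_from_engineering(set$ec)
  pr <- ramp_protocol(0.01, 0.1, 100)
  r <- seq(0, 1, by = 0.1)
  rf <- radial_fields(C, set$tp, pr, r, c(5, 10, 30, 500), n_roots = 40)
  # axis pinned, free-draining lateral surface
  expect_equal(rf$u_over_a[1, ], rep(0, 4), tolerance = 1e-14)
  expect_equal(rf$p_kPa[11, ], rep(0, 4), tolerance = 1e-10)
  expect_true(all(is.finite(rf$u_over_a)), all(is.finite(rf$p_kPa)))
  # drained equilibrium: u_r/a -> -nu31 eps0 (r/a)
  expect_equal(rf$u_over_a[11, 4], -0.24 * 0.1, tolerance = 1e-6)
  expect_equal(rf$u_over_a[, 4], -0.24 * 0.1 * r, tolerance = 1e-6)
  # fluid drawn inward during the hold (tension sucks fluid in)
  expect_true(all(rf$w_over_a[11, 1:3] < 0))
  expect_error(radial_fields(C, set$tp, pr, c(-0.1, 0.5), 1), "r_grid")
})

test_that("instantaneous step displacement is the isochoric field", {
  set <- anchor_50()
  C <- stiffness_from_engineering(set$ec)
  rf <- radial_fields(C, set$tp, ramp_protocol(Inf, 0.1),
                      seq(0, 0.8, by = 0.2), 1e-5 * set$tp$tg, n_roots = 400)
  # u(r, 0+) = -eps0 r / 2 pointwise away from the boundary layer
  expect_equal(as.numeric(rf$u_over_a), -0.05 * seq(0, 0.8, by = 0.2),
               tolerance = 2e-3)
})
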