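# Solver fixtures share the tauD = 100 ns, R0 = 10 A, rL = 2.5 A
# photophysics; tolerances follow the stated solver contracts.

test_that("time-integrated solve hits the closed-form limits", {
  fx <- fig_fixture()
  L <- static_limit_L(fx$dist, fx$photo$R0)
  R <- dynamic_limit_R(fx$dist)
  s0 <- solve_time_integrated(hse_problem(fx$dist, fx$photo, 0))
  expect_lt(abs(s0$R_eff - L) / L, 0.002)
  sInf <- solve_time_integrated(hse_problem(fx$dist, fx$photo, 1e4 *
                                              fx$photo$R0^2 /
                                              fx$photo$tau_D))
  expect_lt(abs(sInf$R_eff - R) / R, 0.002)
})

test_that("at D = 0 the boundary-value problem decouples pointwise", {
  fx <- fig_fixture()
  pr <- hse_problem(fx$dist, fx$photo, 0)
  s <- dfret:::hse_setup(pr)
  nfield <- dfret:::tridiag_solve(s$op$ml, s$op$md, s$op$mu, -s$p)
  expected <- s$p * fx$photo$tau_D /
    (1 + (fx$photo$R0 / s$r)^6)
  expect_equal(nfield, expected, tolerance = 1e-12)
})

test_that("time-domain and time-integrated solvers agree to 1e-4 in E", {
  fx <- fig_fixture()
  for (D in c(0, 0.01, 0.3, 1, 5, 100, 1e4)) {
    ti <- solve_time_integrated(hse_problem(fx$dist, fx$photo, D))
    td <- solve_time_domain(hse_problem(fx$dist, fx$photo, D))
    expect_lt(abs(ti$E - td$E), 1e-4)
  }
})

test_that("survival trace is sane and decay-only reduces to exp(-t/tauD)", {
  fx <- fig_fixture()
  td <- solve_time_domain(hse_problem(fx$dist, fx$photo, 1))
  expect_equal(td$survival$Q[1], 1, tolerance = 1e-10)
  expect_true(all(diff(td$survival$Q) <= 1e-12))

  nosink <- solve_time_domain(hse_problem(fx$dist, fx$photo, 1),
                              include_sink = FALSE)
  expect_identical(nosink$E, 0)
  expect_lt(max(abs(nosink$survival$Q -
                      exp(-nosink$survival$t_ns / 100))), 1e-6)
})

test_that("zero-flux walls conserve mass when decay and sink are off", {
  fx <- fig_fixture()
  cons <- solve_time_domain(hse_problem(fx$dist, fx$photo, 5),
                            include_decay = FALSE, include_sink = FALSE)
  expect_lt(cons$diagnostics$mass_drift, 1e-8)
})

test_that("spatial discretization converges at second order", {
  fx <- fig_fixture()
  E <- vapply(c(800L, 1600L, 3200L), function(ns)
    solve_time_integrated(hse_problem(fx$dist, fx$photo, 1,
                                      n_space = ns))$E, 0)
  d1 <- abs(E[2] - E[1]); d2 <- abs(E[3] - E[2])
  # clean h^2 behaviour; the absolute level at n = 800 is ~1e-5
  expect_lt(d1, 1e-5)
  expect_gt(d1 / d2, 3); expect_lt(d1 / d2, 5)
})

test_that("effective distance is monotone non-increasing in D", {
  fx <- fig_fixture()
  reff <- vapply(default_D_grid(16), function(D)
    solve_time_integrated(hse_problem(fx$dist, fx$photo, D))$R_eff, 0)
  expect_true(all(diff(reff) <= 1e-3))
})

test_that("rescaled (s, z) solve matches the unscaled solve", {
  fx <- fig_fixture()
  for (D in c(0.01, 1, 100)) {
    pr <- hse_problem(fx$dist, fx$photo, D)
    expect_lt(abs(rescaled_solve(pr)$R_eff -
                    solve_time_integrated(pr)$R_eff), 1e-4)
  }
})

test_that("ES2: (D, tauD) -> (c D, tauD / c) leaves E unchanged", {
  fx <- fig_fixture()
  E1 <- solve_time_integrated(hse_problem(fx$dist,
                                          photophysics(100, 10), 2))$E
  E2 <- solve_time_integrated(hse_problem(fx$dist,
                                          photophysics(10, 10), 20))$E
  expect_lt(abs(E1 - E2), 1e-6)
})

test_that("ES4: equal J and equal R0/rL give equal DI", {
  dA <- distance_distribution("ideal_chain_shifted", b = 24, rL = 4)
  dB <- distance_distribution("ideal_chain_shifted", b = 18, rL = 3)
  pA <- photophysics(100, 12); pB <- photophysics(50, 9)
  J <- augmented_J(2, 100, 12)$J
  DB <- J * pB$R0^2 / pB$tau_D
  a <- solve_time_integrated(hse_problem(dA, pA, 2))
  b <- solve_time_integrated(hse_problem(dB, pB, DB))
  diA <- diffusion_influence(a$R_eff, static_limit_L(dA, 12),
                             dynamic_limit_R(dA))
  diB <- diffusion_influence(b$R_eff, static_limit_L(dB, 9),
                             dynamic_limit_R(dB))
  expect_lt(abs(diA - diB), 1e-3)
})

test_that("problem constructor validates its invariants", {
  fx <- fig_fixture()
  expect_error(hse_problem(fx$dist, fx$photo, -1), "'D'")
  expect_error(hse_problem(fx$dist, fx$photo, 1, n_space = 100),
               "at least 200")
})
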