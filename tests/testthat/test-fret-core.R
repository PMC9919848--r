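test_that("Foerster-law conversions are exact mutual inverses", {
  p <- photophysics(100, 10)
  expect_equal(forster_rate(p, 10), p$k_D, tolerance = 1e-14)
  expect_equal(forster_rate(p, 20), 0.01 / 64, tolerance = 1e-14)
  r <- seq(2, 40, length.out = 50)
  expect_true(all(diff(forster_rate(p, r)) < 0))
  expect_error(forster_rate(p, 0), "positive")

  expect_equal(kfret_from_rates(0.02, 0.01), 0.01)
  expect_equal(kfret_from_rates(0.011, 0.010), 0.001, tolerance = 1e-12)
  expect_identical(kfret_from_rates(0.01, 0.01), 0)
  expect_error(kfret_from_rates(0.009, 0.01), "negative transfer")

  expect_equal(reff_from_kfret(p$k_D, p), 10, tolerance = 1e-12)
  expect_equal(reff_from_kfret(64 * p$k_D, p), 5, tolerance = 1e-12)
  for (x in c(3, 7.7, 10, 23)) {
    expect_equal(reff_from_kfret(p$k_D * (10 / x)^6, p), x,
                 tolerance = 1e-12)
  }

  expect_equal(efficiency_to_reff(0.5, 10), 10, tolerance = 1e-12)
  expect_equal(efficiency_to_reff(64 / 65, 10), 5, tolerance = 1e-12)
  for (E in c(1e-4, 0.2, 0.5, 0.93, 1 - 1e-6)) {
    expect_equal(reff_to_efficiency(efficiency_to_reff(E, 12), 12), E,
                 tolerance = 1e-12)
  }
  expect_error(efficiency_to_reff(0, 10), "no transfer")
  expect_error(efficiency_to_reff(1, 10), "undefined")
})

test_that("photophysics enforces its rate identities", {
  p <- photophysics(100, 12)
  expect_lt(abs(p$k_D * p$tau_D - 1), 1e-12)
  expect_silent(photophysics(100, 12, k_rad = 0.004, k_nrad = 0.006))
  expect_error(photophysics(100, 12, k_rad = 0.004, k_nrad = 0.01),
               "k_rad")
})

test_that("static limit: degenerate case, oracle, shift monotonicity", {
  nd <- distance_distribution("skewed_gaussian_shifted", b = 2, a = 400,
                              rL = 8, rR = 12)   # near-delta at ~10 A
  expect_lt(abs(static_limit_L(nd, 10) - 10), 0.001 * 10)

  d <- distance_distribution("ideal_chain_shifted", b = 18, rL = 3)
  expect_lt(abs(static_limit_L(d, 9) - oracle_static_L(d, 9, n = 1e6)),
            1e-6 * oracle_static_L(d, 9, n = 1e6))

  # rigid rightward shift of the whole distribution increases L
  d_shift <- distance_distribution("ideal_chain_shifted", b = 18, rL = 5,
                                   rR = d$rR + 2)
  expect_gt(static_limit_L(d_shift, 9), static_limit_L(d, 9))
})

test_that("dynamic limit: degenerate case, oracle, and R <= L", {
  nd <- distance_distribution("skewed_gaussian_shifted", b = 2, a = 400,
                              rL = 8, rR = 12)
  expect_lt(abs(dynamic_limit_R(nd) - 10), 0.001 * 10)

  d <- distance_distribution("ideal_chain_shifted", b = 18, rL = 3)
  expect_lt(abs(dynamic_limit_R(d) - oracle_dynamic_R(d, n = 1e6)),
            1e-6 * oracle_dynamic_R(d))

  # property: L >= R across a parameter sweep
  for (b in c(10, 18, 26)) {
    for (rL in c(2, 3.5)) {
      di <- distance_distribution("ideal_chain_shifted", b = b, rL = rL)
      for (R0 in c(9, 12, 15)) {
        expect_gte(static_limit_L(di, R0), dynamic_limit_R(di))
      }
    }
  }
})

test_that("efficiency route reproduces the closed-form static limit", {
  d <- distance_distribution("ideal_chain_shifted", b = 22, rL = 3)
  R0 <- 11
  E_static <- stats::integrate(function(r)
    evaluate_pdf(d, r) * R0^6 / (r^6 + R0^6), d$rL, d$rR,
    rel.tol = 1e-12, abs.tol = 1e-14)$value
  expect_equal(efficiency_to_reff(E_static, R0), static_limit_L(d, R0),
               tolerance = 1e-10)
})

test_that("augmented diffusion coefficient is dimensionless and invariant", {
  j <- augmented_J(1, 100, 10)
  expect_identical(j$J, 1)
  expect_identical(j$X, 1)
  expect_equal(augmented_J(10, 10, 10)$J, augmented_J(1, 100, 10)$J)
  expect_equal(augmented_J(2.5, 80, 12)$X, sqrt(2.5 * 80) / 12,
               tolerance = 1e-14)
})

test_that("diffusion influence: endpoints, linearity, guards", {
  expect_identical(diffusion_influence(18, L = 18, R = 14), 0)
  expect_identical(diffusion_influence(14, L = 18, R = 14), 1)
  expect_equal(diffusion_influence(16, L = 18, R = 14), 0.5)
  # clipping window
  expect_identical(diffusion_influence(18.002, L = 18, R = 14), 0)
  expect_error(diffusion_influence(18.2, L = 18, R = 14), "clipping")
  expect_error(diffusion_influence(16, L = 14, R = 18), "L > R")
  expect_error(diffusion_influence(15, L = 15.0000005, R = 15),
               "amplitude")
})
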