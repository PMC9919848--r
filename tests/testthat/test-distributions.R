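test_that("all four models construct normalized densities", {
  cases <- list(
    distance_distribution("ideal_chain_legacy", b = 18, rL = 2, rR = 90),
    distance_distribution("ideal_chain_shifted", b = 18, rL = 3),
    distance_distribution("skewed_gaussian_legacy", b = 15, a = 0.02,
                          rL = 2, rR = 80),
    distance_distribution("skewed_gaussian_shifted", b = 15, a = 0.02,
                          rL = 3))
  for (d in cases) {
    total <- stats::integrate(function(r) evaluate_pdf(d, r),
                              d$rL, d$rR, rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-8)
    expect_true(all(evaluate_pdf(d, seq(d$rL, d$rR, length.out = 200))
                    >= 0))
  }
})

test_that("normalization is idempotent and matches the dense-grid oracle", {
  d <- distance_distribution("ideal_chain_shifted", b = 18, rL = 3,
                             rR = 120)
  d2 <- normalize(d)
  expect_lt(abs(d$norm - d2$norm), 1e-12 * abs(d$norm))
  z_oracle <- trapz_oracle(function(r) dfret:::dist_kernel(d, r),
                           3, 120, n = 1e6)
  expect_lt(abs(1 / d$norm - z_oracle), 1e-7 * z_oracle)
})

test_that("truncation is honored: small rR still integrates to one", {
  # rR cuts off well over 1% of the untruncated kernel mass
  d <- distance_distribution("ideal_chain_shifted", b = 20, rL = 3,
                             rR = 20)
  total <- stats::integrate(function(r) evaluate_pdf(d, r), 3, 20,
                            rel.tol = 1e-10)$value
  expect_lt(abs(total - 1), 1e-8)
})

test_that("shifted kernels vanish continuously at rL", {
  d <- distance_distribution("ideal_chain_shifted", b = 20, rL = 3)
  expect_identical(evaluate_pdf(d, 3), 0)
  eps <- 10^seq(-1, -6)
  expect_true(all(diff(evaluate_pdf(d, 3 + eps)) < 0))
  g <- distance_distribution("skewed_gaussian_shifted", b = 15, a = 0.02,
                             rL = 2.5)
  expect_identical(evaluate_pdf(g, 2.5), 0)
})

test_that("shifted model with rL = 0 coincides with the legacy model", {
  s <- distance_distribution("ideal_chain_shifted", b = 16, rL = 0,
                             rR = 80)
  l <- distance_distribution("ideal_chain_legacy", b = 16, rL = 0,
                             rR = 80)
  r <- seq(0.01, 79, length.out = 300)
  expect_equal(evaluate_pdf(s, r), evaluate_pdf(l, r), tolerance = 1e-12)
})

test_that("legacy ideal chain has root-mean-square distance b", {
  b <- 17.3
  d <- distance_distribution("ideal_chain_legacy", b = b, rL = 0,
                             rR = 12 * b)
  m2 <- stats::integrate(function(r) evaluate_pdf(d, r) * r^2, 0, 12 * b,
                         rel.tol = 1e-10)$value
  expect_lt(abs(sqrt(m2) - b), 1e-6 * b)
})

test_that("evaluate_pdf rejects out-of-support distances", {
  d <- distance_distribution("ideal_chain_shifted", b = 20, rL = 3)
  expect_error(evaluate_pdf(d, 2.9), "support")
  expect_error(evaluate_pdf(d, d$rR + 1), "support")
})

test_that("inverse sixth moment: degenerate limit, oracle, monotonicity", {
  # near-delta at r* = 10 A (huge skew parameter pins the density)
  nd <- distance_distribution("skewed_gaussian_shifted", b = 2, a = 400,
                              rL = 8, rR = 12)
  expect_lt(abs(inverse_sixth_moment(nd) - 1e-6), 1e-3 * 1e-6)

  d <- distance_distribution("ideal_chain_shifted", b = 18, rL = 3,
                             rR = 120)
  kern <- function(r) dfret:::dist_kernel(d, r)
  z <- trapz_oracle(kern, 3, 120, n = 1e6)
  oracle <- trapz_oracle(function(r) kern(r) / z / r^6, 3, 120, n = 1e6)
  expect_lt(abs(inverse_sixth_moment(d) - oracle), 1e-6 * oracle)

  d_half <- distance_distribution("ideal_chain_shifted", b = 18,
                                  rL = 1.5, rR = 120)
  expect_gt(inverse_sixth_moment(d_half), inverse_sixth_moment(d))

  d0 <- distance_distribution("ideal_chain_legacy", b = 18, rL = 0,
                              rR = 120)
  expect_error(inverse_sixth_moment(d0), "diverges")
})

test_that("sampling is reproducible, in-support and distributionally correct", {
  d <- distance_distribution("ideal_chain_shifted", b = 20, rL = 3)
  s1 <- sample_dist(d, 1e5, seed = 42)
  s2 <- sample_dist(d, 1e5, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1 >= d$rL & s1 <= d$rR))

  mean_quad <- stats::integrate(function(r) r * evaluate_pdf(d, r),
                                d$rL, d$rR, rel.tol = 1e-10)$value
  sd_quad <- sqrt(stats::integrate(function(r)
    (r - mean_quad)^2 * evaluate_pdf(d, r), d$rL, d$rR,
    rel.tol = 1e-10)$value)
  expect_lt(abs(mean(s1) - mean_quad), 3 * sd_quad / sqrt(1e5))

  tab <- dfret:::dist_table(d)
  ks <- suppressWarnings(
    stats::ks.test(s1, stats::approxfun(tab$r, tab$cdf,
                                        rule = 2))$statistic)
  expect_lt(ks, 0.01)
})

test_that("choose_rR encloses the stated tail mass and is monotone", {
  rR <- choose_rR("ideal_chain_shifted", b = 30, rL = 5,
                  tail_tolerance = 1e-6)
  proto <- distance_distribution("ideal_chain_shifted", b = 30, rL = 5,
                                 rR = rR + 400, normalize = TRUE)
  tail <- stats::integrate(function(r) evaluate_pdf(proto, r), rR,
                           rR + 400, rel.tol = 1e-8,
                           abs.tol = 1e-14)$value
  expect_lt(tail, 1e-6)
  expect_gte(rR, choose_rR("ideal_chain_shifted", b = 30, rL = 5,
                           tail_tolerance = 1e-4))
  expect_gt(choose_rR("ideal_chain_shifted", b = 60, rL = 5), rR)
})
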