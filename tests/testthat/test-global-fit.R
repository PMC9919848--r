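test_that("intensity ratios convert to effective distances", {
  expect_equal(reff_from_intensity(50, 100, 10), 10, tolerance = 1e-12)
  expect_equal(reff_from_intensity(100 / 65, 100, 10), 5,
               tolerance = 1e-12)
  r <- reff_from_intensity(30, 100, 12)
  expect_equal(1 - 30 / 100, reff_to_efficiency(r, 12),
               tolerance = 1e-12)
  expect_error(reff_from_intensity(100, 100, 10), "no transfer")
  expect_error(reff_from_intensity(-1, 100, 10), "positive")
})

test_that("model predictions behave like the underlying sigmoid", {
  params <- list(D_ref = 1, b = 24, rL = 4)
  cond <- conditions_table("c", 100, 12, 1)
  dist <- dfret:::build_fit_dist(24, 4)
  L <- static_limit_L(dist, 12)

  # static endpoint as the viscosity knob goes to zero
  tiny <- predict_reff(params, conditions_table("c", 100, 12, 1e-12))
  expect_lt(abs(tiny - L), 1e-4)

  # strictly decreasing in d_scale
  scans <- conditions_table(letters[1:6], 100, 12,
                            c(0.1, 0.3, 1, 3, 10, 30))
  expect_true(all(diff(predict_reff(params, scans)) < 0))

  # against a direct PDE solve
  R <- dynamic_limit_R(dist)
  pde <- solve_time_integrated(hse_problem(dist, photophysics(100, 12),
                                           2))$R_eff
  expect_lt(abs(predict_reff(params, conditions_table("c", 100, 12, 2))
                - pde), 0.01 * (L - R))
})

test_that("zero-noise synthetic data is recovered exactly", {
  truth <- synthetic_truth(b = 24, rL = 4, D_ref = 1, noise_sd = 0,
                           seed = 11)
  obs <- generate_dataset(truth)
  fit <- fit_global(obs, model0 = list(D_ref = 4, b = 17, rL = 3,
                                       free = c("D_ref", "b", "rL")),
                    starts = 4L, seed = 3)
  expect_lt(abs(fit$estimates$D_ref / 1 - 1), 0.02)
  expect_lt(abs(fit$estimates$b / 24 - 1), 0.02)
  expect_lt(abs(fit$estimates$rL - 4), 0.2)
})

test_that("starting at the truth is a fixed point", {
  truth <- synthetic_truth(b = 24, rL = 4, D_ref = 1, noise_sd = 0,
                           seed = 11)
  obs <- generate_dataset(truth)
  fit <- fit_global(obs, model0 = list(D_ref = 1, b = 24, rL = 4,
                                       free = c("D_ref", "b")),
                    starts = 1L, seed = 1)
  expect_lt(fit$ssr, 1e-12)
  expect_lt(abs(fit$estimates$D_ref - 1), 1e-4)
  expect_lt(abs(fit$estimates$b - 24), 1e-3)
})

test_that("fit is invariant to row order and common sigma rescaling", {
  truth <- synthetic_truth(b = 24, rL = 4, D_ref = 1, noise_sd = 0.2,
                           seed = 4)
  obs <- generate_dataset(truth)
  m0 <- list(D_ref = 2, b = 20, rL = 4, free = c("D_ref", "b"))
  f1 <- fit_global(obs, m0, starts = 2L, seed = 5)
  f2 <- fit_global(obs[rev(seq_len(nrow(obs))), ], m0, starts = 2L,
                   seed = 5)
  expect_equal(f1$estimates$D_ref, f2$estimates$D_ref,
               tolerance = 1e-6)
  obs3 <- obs; obs3$sigma_angstrom <- obs3$sigma_angstrom * 10
  f3 <- fit_global(obs3, m0, starts = 2L, seed = 5)
  expect_equal(f1$estimates$D_ref, f3$estimates$D_ref,
               tolerance = 1e-4)
  expect_equal(f3$ssr, f1$ssr / 100, tolerance = 1e-6)
})

test_that("profile likelihood: fixing D at half/double truth raises SSR", {
  truth <- synthetic_truth(b = 24, rL = 4, D_ref = 1, noise_sd = 0,
                           seed = 11)
  obs <- generate_dataset(truth)
  ssr_at <- function(dref) {
    fit_global(obs, list(D_ref = dref, b = 24, rL = 4,
                         free = c("b")), starts = 2L, seed = 1)$ssr
  }
  expect_gt(ssr_at(0.5), 1e3 * max(ssr_at(1), 1e-18))
  expect_gt(ssr_at(2), 1e3 * max(ssr_at(1), 1e-18))
})

test_that("degenerate designs are reported, not silently fitted", {
  cond <- conditions_table(letters[1:4], 100, 12, rep(2, 4))
  obs <- cond
  obs$reff_angstrom <- rep(16, 4)
  obs$sigma_angstrom <- rep(0.2, 4)
  expect_error(fit_global(obs, list(D_ref = 1, b = 24, rL = 4,
                                    free = c("D_ref", "b"))),
               "unidentifiable")
})
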