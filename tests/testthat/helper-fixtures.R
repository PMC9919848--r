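# Shared fixtures and independent oracles, rebuilt in code at test time.

# Reference sigmoid coefficients for the calibration grid (the primary
# quantitative surface): ratio rho = R0/rL, fitted midpoint X0 and
# steepness M per (R0, rL) combination with b = 2 R0, tau_D = 100 ns.
ref_sigmoid_table <- data.frame(
  ratio = c(3, 3, 3, 4, 4, 4, 5, 5, 6, 6, 6),
  R0    = c(9, 12, 15, 10, 12, 14, 10, 15, 9, 12, 15),
  rL    = c(3, 4, 5, 2.5, 3, 3.5, 2, 3, 1.5, 2, 2.5),
  X0    = c(0.8935, 0.8929, 0.8933, 1.1722, 1.1719, 1.1724,
            1.4259, 1.4256, 1.6591, 1.6592, 1.6587),
  M     = c(1.7823, 1.7876, 1.7861, 1.6513, 1.6532, 1.6494,
            1.5387, 1.5391, 1.4481, 1.4483, 1.4483))

# Standard calibration fixture: shifted ideal chain, b = 2 R0.
make_calib_dist <- function(R0, rL) {
  distance_distribution("ideal_chain_shifted", b = 2 * R0, rL = rL)
}

# Broad single-peak test fixture at the tauD = 100 ns, R0 = 10 A,
# rL = 2.5 A photophysics used throughout the solver tests.
fig_fixture <- function() {
  list(dist = distance_distribution("ideal_chain_shifted", b = 20,
                                    rL = 2.5),
       photo = photophysics(100, 10))
}

# Trio of visibly different well-behaved skewed Gaussians sharing
# (tauD, R0, rL): the cross-shape profile-collapse fixture.
shape_trio <- function(rL = 2.5) {
  list(distance_distribution("skewed_gaussian_shifted", a = 0.015,
                             b = 14, rL = rL),
       distance_distribution("skewed_gaussian_shifted", a = 0.008,
                             b = 18, rL = rL),
       distance_distribution("skewed_gaussian_shifted", a = 0.02,
                             b = 11, rL = rL))
}

# Dense-grid trapezoid quadrature: the independent oracle against which
# the adaptive-quadrature code paths are checked.
trapz_oracle <- function(f, lo, hi, n = 2e5) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  h <- x[2] - x[1]
  sum((y[-1] + y[-n]) / 2) * h
}

# Oracle for the static limit: Eq.-style dense-grid evaluation using only
# the raw kernel (independent of the package's normalize/integrate path).
oracle_static_L <- function(dist, R0, n = 2e5) {
  kern <- function(r) dfret:::dist_kernel(dist, r)
  z <- trapz_oracle(kern, dist$rL, dist$rR, n)
  S <- trapz_oracle(function(r) kern(r) / z * r^6 / (r^6 + R0^6),
                    dist$rL, dist$rR, n)
  R0 * (1 / (1 - S) - 1)^(1 / 6)
}

oracle_dynamic_R <- function(dist, n = 2e5) {
  kern <- function(r) dfret:::dist_kernel(dist, r)
  z <- trapz_oracle(kern, dist$rL, dist$rR, n)
  m6 <- trapz_oracle(function(r) kern(r) / z / r^6, dist$rL, dist$rR, n)
  m6^(-1 / 6)
}
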