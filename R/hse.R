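#' Define a Haas-Steinberg solve
#'
#' Couples a distance distribution, donor photophysics and an intrachain
#' diffusion coefficient into one reaction-diffusion problem for the
#' excited-donor population N(r, t):
#'
#' \deqn{\partial_t N = -N/\tau_D - (R_0/r)^6 N/\tau_D +
#'       \partial_r ( D N_0 \partial_r (N/N_0) )}
#'
#' with N(r, 0) = N0(r) = p(r) and zero-flux (reflecting) walls at rL and
#' rR. The diffusion operator has p(r) as its equilibrium density, so total
#' population is conserved when decay and sink are switched off.
#'
#' @param dist a normalized \code{dfret_dist}; its \code{[rL, rR]} is the
#'   spatial domain.
#' @param photo a \code{dfret_photo}.
#' @param D intrachain diffusion coefficient, A^2/ns (\code{>= 0}).
#' @param n_space number of uniform spatial nodes (\code{>= 200}).
#' @param solver_mode \code{"time_integrated"} (default; direct linear
#'   solve for the time integral of N, no time stepping) or
#'   \code{"time_domain"} (stiff theta-method march, used as a validation
#'   oracle).
#' @param time_horizon_factor cap on the integration horizon in units of
#'   tau_D (time_domain only); stepping stops earlier once the residual
#'   survival drops below 1e-8.
#' @param dt_factor time step in units of tau_D (time_domain only).
#' @return an object of class \code{dfret_hse_problem}.
#' @export
hse_problem <- function(dist, photo, D, n_space = 800L,
                        solver_mode = c("time_integrated", "time_domain"),
                        time_horizon_factor = 60, dt_factor = 5e-4) {
  stopifnot(inherits(dist, "dfret_dist"), inherits(photo, "dfret_photo"))
  solver_mode <- match.arg(solver_mode)
  if (!is.finite(D) || D < 0) stop("'D' must be >= 0")
  if (n_space < 200L) stop("'n_space' must be at least 200")
  structure(list(dist = dist, photo = photo, D = D,
                 n_space = as.integer(n_space), solver_mode = solver_mode,
                 time_horizon_factor = time_horizon_factor,
                 dt_factor = dt_factor),
            class = "dfret_hse_problem")
}

# Finite-volume discretization of the conservative diffusion operator
# d/dr ( D N0 d(n/N0)/dr ) on a uniform vertex-centred grid. Face
# conductance is the harmonic mean of N0 at the adjacent nodes; faces
# touching a node with N0 <= eps carry zero flux (the well-behaved
# endpoints, where the exact population also vanishes). Returns the
# tridiagonal bands of the full operator M = -diag(kdia) + diffusion and
# the quadrature weights (trapezoid: h, with h/2 at the walls).
hse_operator <- function(r, p, kdia, D) {
  n <- length(r)
  h <- r[2L] - r[1L]
  w <- rep(h, n); w[c(1L, n)] <- h / 2
  eps <- 1e-12 * max(p)
  pj <- p[-n]; pj1 <- p[-1L]
  ok <- pj > eps & pj1 > eps
  g <- ifelse(ok, 2 * pj * pj1 / (pj + pj1), 0)   # face conductance
  af <- ifelse(ok, D * g / (h * pj1), 0)          # F_j = af n_{j+1} - bf n_j
  bf <- ifelse(ok, D * g / (h * pj), 0)
  ml <- c(0, bf / w[-1L])                         # sub-diagonal
  mu <- c(af / w[-n], 0)                          # super-diagonal
  md <- -kdia
  md[-n] <- md[-n] - bf / w[-n]
  md[-1L] <- md[-1L] - af / w[-1L]
  list(ml = ml, md = md, mu = mu, w = w, h = h)
}

# Shared setup: grid, discretely renormalized density, sink+decay rates.
hse_setup <- function(problem, include_decay = TRUE, include_sink = TRUE) {
  dist <- problem$dist; photo <- problem$photo
  n <- problem$n_space
  r <- seq(dist$rL, dist$rR, length.out = n)
  p <- evaluate_pdf(dist, r)
  h <- r[2L] - r[1L]
  w <- rep(h, n); w[c(1L, n)] <- h / 2
  p <- p / sum(w * p)   # exact discrete normalization
  kdia <- numeric(n)
  if (include_decay) kdia <- kdia + photo$k_D
  if (include_sink) {
    sink <- photo$k_D * (photo$R0 / r)^6
    kdia <- kdia + sink
  }
  op <- hse_operator(r, p, kdia, problem$D)
  list(r = r, p = p, kdia = kdia, op = op)
}

hse_solution <- function(E, photo, problem, diagnostics = list(),
                         survival = NULL) {
  if (E <= 0) stop("non-positive transfer efficiency: ",
                   "effective distance undefined")
  structure(list(E = E,
                 R_eff = efficiency_to_reff(E, photo$R0),
                 D = problem$D,
                 J = augmented_J(problem$D, photo$tau_D, photo$R0)$J,
                 solver_mode = problem$solver_mode,
                 survival = survival,
                 diagnostics = diagnostics,
                 converged = TRUE),
            class = "dfret_hse_solution")
}

#' @export
print.dfret_hse_solution <- function(x, ...) {
  cat(sprintf("<dfret_hse_solution> %s: E = %.6f, R_eff = %.4f A (D = %g A^2/ns, J = %g)\n",
              x$solver_mode, x$E, x$R_eff, x$D, x$J))
  invisible(x)
}

#' Time-integrated (boundary-value) solve
#'
#' Integrating the population equation over all time turns it into a
#' linear two-point boundary-value problem for the time-integrated field
#' \code{n(r) = int_0^inf N(r, t) dt}:
#' \deqn{-p(r) = -(1/\tau_D)(1 + (R_0/r)^6) n(r) +
#'       \partial_r ( D N_0 \partial_r (n/N_0) )}
#' which is solved directly as one sparse tridiagonal system; the transfer
#' efficiency is \code{E = 1 - (1/tau_D) int n dr}. This is the production
#' path: deterministic and orders of magnitude faster than time stepping.
#'
#' @param problem a \code{dfret_hse_problem}.
#' @return a \code{dfret_hse_solution} with fields \code{E}, \code{R_eff},
#'   \code{J} and diagnostics.
#' @export
solve_time_integrated <- function(problem) {
  stopifnot(inherits(problem, "dfret_hse_problem"))
  problem$solver_mode <- "time_integrated"
  s <- hse_setup(problem)
  nfield <- tridiag_solve(s$op$ml, s$op$md, s$op$mu, -s$p)
  if (any(!is.finite(nfield)))
    stop("singular or ill-conditioned system; try refining the grid ",
         "(larger n_space)")
  tau_D <- problem$photo$tau_D
  E <- 1 - sum(s$op$w * nfield) / tau_D
  # discrete balance: p-mass must equal decay+transfer mass
  mass_residual <- abs(sum(s$op$w * s$p) -
                         sum(s$op$w * s$kdia * nfield))
  hse_solution(E, problem$photo, problem,
               diagnostics = list(mass_residual = mass_residual,
                                  min_n = min(nfield)))
}

#' Time-domain solve
#'
#' Marches the stiff population equation with the theta method
#' (Crank-Nicolson after a short implicit-Euler startup that damps the
#' fast r^-6 sink transients), accumulates the survival
#' \code{Q(t) = int N dr}, and completes the tail beyond the horizon with
#' the terminal single-exponential rate. Retained as the validation oracle
#' for [solve_time_integrated()].
#'
#' @param problem a \code{dfret_hse_problem}.
#' @param include_decay,include_sink switch off the donor-decay or
#'   transfer-sink term (validation only: with both off, total population
#'   is conserved; with only the sink off, \code{Q(t) = exp(-t/tau_D)}).
#' @return a \code{dfret_hse_solution}; \code{$survival} holds the
#'   \code{(t_ns, Q)} table.
#' @export
solve_time_domain <- function(problem, include_decay = TRUE,
                              include_sink = TRUE) {
  stopifnot(inherits(problem, "dfret_hse_problem"))
  problem$solver_mode <- "time_domain"
  s <- hse_setup(problem, include_decay, include_sink)
  tau_D <- problem$photo$tau_D
  dt <- problem$dt_factor * tau_D
  max_steps <- ceiling(problem$time_horizon_factor / problem$dt_factor)

  # Rannacher startup: a few implicit-Euler half-steps kill the stiff
  # sink transients that plain Crank-Nicolson would leave oscillating
  st <- cn_march(s$op$ml, s$op$md, s$op$mu, s$p, s$op$w,
                 dt / 2, qtol = 0, max_steps = 4L, theta = 1)
  run <- cn_march(s$op$ml, s$op$md, s$op$mu, st$N_final, s$op$w,
                  dt, qtol = 1e-8, max_steps = max_steps, theta = 0.5)
  Q <- c(st$Q, run$Q[-1L])
  t <- c(seq(0, 2 * dt, by = dt / 2),
         2 * dt + dt * seq_len(length(run$Q) - 1L))
  K <- length(Q)
  survival <- data.frame(t_ns = t, Q = Q)

  if (!include_decay && !include_sink) {
    # conservation diagnostic only; efficiency is undefined here
    return(structure(list(E = NA_real_, R_eff = NA_real_,
                          D = problem$D, J = NA_real_,
                          solver_mode = "time_domain",
                          survival = survival,
                          diagnostics = list(
                            mass_drift = max(abs(Q - Q[1L]))),
                          converged = TRUE),
                     class = "dfret_hse_solution"))
  }

  integral <- sum(diff(t) * (Q[-1L] + Q[-K]) / 2)
  # tail completion with the terminal decay rate
  lambda <- log(Q[K - 1L] / Q[K]) / (t[K] - t[K - 1L])
  if (is.finite(lambda) && lambda > 0) integral <- integral + Q[K] / lambda

  if (!include_sink) {
    sol <- structure(list(E = 0, R_eff = Inf, D = problem$D,
                          J = augmented_J(problem$D, tau_D,
                                          problem$photo$R0)$J,
                          solver_mode = "time_domain",
                          survival = survival,
                          diagnostics = list(
                            decay_integral = integral / tau_D),
                          converged = TRUE),
                     class = "dfret_hse_solution")
    return(sol)
  }
  E <- 1 - integral / tau_D
  hse_solution(E, problem$photo, problem,
               diagnostics = list(n_steps = run$n_steps, Q_final = Q[K],
                                  horizon_ns = t[K]),
               survival = survival)
}

#' Dimensionless (rescaled) solve
#'
#' Solves the population equation in the rescaled coordinates
#' \code{s = r/R0}, \code{z = t/tau_D}, in which the only remaining
#' coefficients are the augmented diffusion coefficient
#' \code{J = D tau_D / R0^2} and the rescaled support
#' \code{[sL, sR] = [rL/R0, rR/R0]}. The transfer efficiency and effective
#' distance are identical to the unscaled solve; this is the form in which
#' the equivalence statements (invariance under changes of D, tau_D, R0
#' that preserve J and R0/rL) become manifest.
#'
#' @param problem a \code{dfret_hse_problem}.
#' @return a \code{dfret_hse_solution}.
#' @export
rescaled_solve <- function(problem) {
  stopifnot(inherits(problem, "dfret_hse_problem"))
  dist <- problem$dist; photo <- problem$photo
  n <- problem$n_space
  R0 <- photo$R0
  sgrid <- seq(dist$rL / R0, dist$rR / R0, length.out = n)
  p <- R0 * evaluate_pdf(dist, sgrid * R0)   # density in s
  h <- sgrid[2L] - sgrid[1L]
  w <- rep(h, n); w[c(1L, n)] <- h / 2
  p <- p / sum(w * p)
  J <- augmented_J(problem$D, photo$tau_D, R0)$J
  kdia <- 1 + sgrid^(-6)                     # z-units: k_D = 1, R0 = 1
  op <- hse_operator(sgrid, p, kdia, J)
  nfield <- tridiag_solve(op$ml, op$md, op$mu, -p)
  E <- 1 - sum(op$w * nfield)                # tau = 1 in z-units
  problem$solver_mode <- "time_integrated"
  sol <- hse_solution(E, photo, problem,
                      diagnostics = list(rescaled = TRUE, sL = sgrid[1L]))
  sol$solver_mode <- "rescaled"
  sol
}

#' Solve the population equation
#'
#' Front end dispatching on \code{solver_mode}.
#'
#' @param problem a \code{dfret_hse_problem}.
#' @return a \code{dfret_hse_solution}.
#' @export
solve_hse <- function(problem) {
  switch(problem$solver_mode,
         time_integrated = solve_time_integrated(problem),
         time_domain = solve_time_domain(problem))
}
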