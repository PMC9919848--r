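#' Default diffusion-coefficient grid
#'
#' 32 log-spaced values spanning \code{[1e-3, 1e6]} A^2/ns, wide enough to
#' run any physically plausible chain from its static to its dynamic limit.
#'
#' @param n number of values.
#' @param D_min,D_max range in A^2/ns.
#' @return numeric vector of diffusion coefficients.
#' @export
default_D_grid <- function(n = 32L, D_min = 1e-3, D_max = 1e6) {
  exp(seq(log(D_min), log(D_max), length.out = n))
}

#' Compute a diffusion profile Reff(D)
#'
#' One population-equation solve per diffusion coefficient; each entry
#' carries the augmented diffusion coefficient \code{J = D tau_D / R0^2}
#' and its square root \code{X}.
#'
#' @param dist a normalized \code{dfret_dist}.
#' @param photo a \code{dfret_photo}.
#' @param D_values diffusion coefficients, A^2/ns (at least 2; sorted
#'   internally).
#' @param n_space spatial resolution passed to the solver.
#' @param solver \code{"time_integrated"} (default) or
#'   \code{"time_domain"}.
#' @return a \code{dfret_profile}: a data frame with columns
#'   \code{D, J, X, R_eff} plus \code{dist}/\code{photo} attributes.
#' @export
compute_profile <- function(dist, photo, D_values = default_D_grid(),
                            n_space = 800L,
                            solver = c("time_integrated", "time_domain")) {
  solver <- match.arg(solver)
  if (length(D_values) < 2L) stop("need at least 2 diffusion coefficients")
  D_values <- sort(D_values)
  solve_fun <- if (solver == "time_integrated") solve_time_integrated
               else solve_time_domain
  rows <- lapply(D_values, function(D) {
    sol <- tryCatch(
      solve_fun(hse_problem(dist, photo, D, n_space = n_space)),
      error = function(e) e)
    if (inherits(sol, "error"))
      return(data.frame(D = D, J = NA_real_, X = NA_real_,
                        R_eff = NA_real_,
                        error = conditionMessage(sol)))
    jx <- augmented_J(D, photo$tau_D, photo$R0)
    data.frame(D = D, J = jx$J, X = jx$X, R_eff = sol$R_eff,
               error = NA_character_)
  })
  prof <- do.call(rbind, rows)
  structure(prof, dist = dist, photo = photo,
            class = c("dfret_profile", "data.frame"))
}

#' Normalize a diffusion profile to a diffusion-influence profile
#'
#' Maps each effective distance onto \code{DI = (R_eff - L)/(R - L)} using
#' the closed-form static limit \code{L} and dynamic limit \code{R} of the
#' profile's own distribution.
#'
#' @param profile a \code{dfret_profile}.
#' @param L,R override the static/dynamic limits (default: computed from
#'   the profile's distribution and Foerster radius).
#' @return a \code{dfret_di_profile}: data frame with columns
#'   \code{D, J, X, DI} and attributes \code{L}, \code{R}.
#' @export
to_di_profile <- function(profile, L = NULL, R = NULL) {
  stopifnot(inherits(profile, "dfret_profile"))
  dist <- attr(profile, "dist"); photo <- attr(profile, "photo")
  if (is.null(L)) L <- static_limit_L(dist, photo$R0)
  if (is.null(R)) R <- dynamic_limit_R(dist)
  ok <- !is.na(profile$R_eff)
  di <- diffusion_influence(profile$R_eff[ok], L, R)
  out <- data.frame(D = profile$D[ok], J = profile$J[ok],
                    X = profile$X[ok], DI = di)
  structure(out, L = L, R = R, dist = dist, photo = photo,
            class = c("dfret_di_profile", "data.frame"))
}

#' Fit the diffusion-influence sigmoid
#'
#' Least-squares fit of
#' \deqn{DI(X) = \frac{(X/X_0)^M}{1 + (X/X_0)^M}}
#' which is a symmetric logistic in ln X. The fit is parameterized in
#' \code{(ln X0, M)} for conditioning; \code{X0} is the abscissa of 50
#' percent diffusion influence and \code{M} the steepness.
#'
#' @param di_profile a \code{dfret_di_profile} spanning DI < 0.1 and
#'   DI > 0.9 (full-range requirement; otherwise midpoint and steepness
#'   are not both identifiable).
#' @param min_amplitude smallest admissible profile amplitude
#'   \code{L - R} in A (default 1): narrow distributions cannot deliver
#'   well-shaped sigmoids.
#' @return a \code{dfret_sigmoid_fit} with \code{X0}, \code{M},
#'   \code{rms_residual} and \code{asymmetry_diagnostic}.
#' @export
fit_sigmoid <- function(di_profile, min_amplitude = 1) {
  stopifnot(inherits(di_profile, "dfret_di_profile"))
  L <- attr(di_profile, "L"); R <- attr(di_profile, "R")
  if (!is.null(L) && !is.null(R) && (L - R) < min_amplitude)
    stop("profile amplitude L - R = ", signif(L - R, 3),
         " A below min_amplitude = ", min_amplitude,
         " A: sigmoid fit refused")
  di <- di_profile$DI; x <- di_profile$X
  if (min(di) >= 0.1 || max(di) <= 0.9)
    stop("DI profile must span below 0.1 and above 0.9 for the ",
         "sigmoid fit (observed range [", signif(min(di), 3), ", ",
         signif(max(di), 3), "])")
  if (any(x <= 0)) stop("X values must be positive")
  lx <- log(x)
  lx0_start <- stats::approx(di, lx, xout = 0.5, ties = mean)$y
  if (!is.finite(lx0_start)) lx0_start <- stats::median(lx)
  start <- c(lx0 = lx0_start, M = 1.5)
  model <- function(par) stats::plogis(par[2L] * (lx - par[1L]))
  obj <- function(par) sum((di - model(par))^2)
  grad <- function(par) {
    f <- model(par)
    r <- di - f
    fp <- f * (1 - f)
    c(2 * par[2L] * sum(r * fp),        # d/d lnX0
      -2 * sum(r * fp * (lx - par[1L])))  # d/dM
  }
  opt <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000L))
  # polish: a second start from the optimum guards against early stops
  opt <- stats::optim(opt$par, obj, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000L))
  if (opt$convergence != 0)
    stop("sigmoid fit did not converge (start lnX0 = ",
         signif(start[1L], 4), ", M = ", start[2L], ")")
  par <- opt$par
  rms <- sqrt(opt$value / length(di))
  fit <- structure(list(X0 = exp(par[[1L]]), M = par[[2L]],
                        rms_residual = rms,
                        asymmetry_diagnostic = NA_real_,
                        n_points = length(di), L = L, R = R),
                   class = "dfret_sigmoid_fit")
  fit$asymmetry_diagnostic <- symmetry_diagnostic(di_profile, fit)
  fit
}

#' @export
print.dfret_sigmoid_fit <- function(x, ...) {
  cat(sprintf("<dfret_sigmoid_fit> X0 = %.4f, M = %.4f (rms %.2e, asymmetry %.2e, %d points)\n",
              x$X0, x$M, x$rms_residual, x$asymmetry_diagnostic,
              x$n_points))
  invisible(x)
}

#' Point-symmetry diagnostic of a DI profile
#'
#' A converged profile is point symmetric about \code{(ln X0, 0.5)}:
#' \code{DI(ln X0 + u) + DI(ln X0 - u) = 1}. The diagnostic is the maximum
#' absolute deviation from that identity over sampled offsets \code{u}
#' (linear interpolation of the profile in ln X); it is the second
#' numerical-quality control, large values flagging an under-resolved
#' solve.
#'
#' @param di_profile a \code{dfret_di_profile}.
#' @param fit a \code{dfret_sigmoid_fit} for the same profile.
#' @param n_u number of sampled offsets.
#' @return the diagnostic (dimensionless, 0 for a perfect sigmoid).
#' @export
symmetry_diagnostic <- function(di_profile, fit, n_u = 101L) {
  lx <- log(di_profile$X); di <- di_profile$DI
  l0 <- log(fit$X0)
  f <- stats::approxfun(lx, di, rule = 1)
  u_max <- min(l0 - min(lx), max(lx) - l0)
  if (u_max <= 0) return(NA_real_)
  u <- seq(0, u_max, length.out = n_u)
  max(abs(f(l0 + u) + f(l0 - u) - 1))
}

#' Full profile-and-fit pipeline for one parameter set
#'
#' Convenience wrapper: compute the diffusion profile, normalize it with
#' the closed-form limits, and fit the sigmoid.
#'
#' @inheritParams compute_profile
#' @inheritParams fit_sigmoid
#' @return a \code{dfret_sigmoid_fit}.
#' @export
profile_and_fit <- function(dist, photo, D_values = default_D_grid(),
                            n_space = 800L, min_amplitude = 1) {
  prof <- compute_profile(dist, photo, D_values, n_space = n_space)
  fit_sigmoid(to_di_profile(prof), min_amplitude = min_amplitude)
}

#' Write or read a diffusion(-influence) profile as CSV
#'
#' Columns \code{D_A2_per_ns, J, X, Reff_angstrom} and, when present,
#' \code{DI}.
#'
#' @param profile a \code{dfret_profile} or \code{dfret_di_profile}.
#' @param file path.
#' @export
write_profile_csv <- function(profile, file) {
  df <- as.data.frame(profile)
  names(df)[names(df) == "D"] <- "D_A2_per_ns"
  names(df)[names(df) == "R_eff"] <- "Reff_angstrom"
  df$error <- NULL
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
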