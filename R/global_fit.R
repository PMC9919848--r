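#' Effective distance from steady-state intensities
#'
#' Steady-state measurements on the donor-acceptor and donor-only
#' constructs give the transfer efficiency \code{E = 1 - I_DA/I_D}; the
#' effective distance follows by inverting Foerster's law.
#'
#' @param I_DA fluorescence intensity of the donor-acceptor construct.
#' @param I_D fluorescence intensity of the donor-only construct.
#' @param R0 Foerster radius, A.
#' @return effective distance in A.
#' @export
reff_from_intensity <- function(I_DA, I_D, R0) {
  if (any(I_DA <= 0)) stop("I_DA must be positive")
  if (any(I_DA >= I_D))
    stop("I_DA >= I_D: no transfer, effective distance undefined")
  efficiency_to_reff(1 - I_DA / I_D, R0)
}

#' Experimental conditions table
#'
#' One row per measurement condition: donor lifetime, Foerster radius and
#' a dimensionless multiplier \code{d_scale} on the reference diffusion
#' coefficient (the viscosity/viscogen knob: \code{D = D_ref * d_scale}).
#'
#' @param label condition labels.
#' @param tau_D donor lifetimes, ns.
#' @param R0 Foerster radii, A.
#' @param d_scale diffusion multipliers (positive).
#' @return a data frame with columns
#'   \code{label, tau_d_ns, r0_angstrom, d_scale}.
#' @export
conditions_table <- function(label, tau_D, R0, d_scale) {
  stopifnot(all(tau_D > 0), all(R0 > 0), all(d_scale > 0))
  data.frame(label = as.character(label), tau_d_ns = tau_D,
             r0_angstrom = R0, d_scale = d_scale)
}

# Distribution builder used by the fitting layer and the synthetic
# generator: shifted ideal chain with a fixed cheap enclosing rule for the
# right limit (tail mass beyond rL + 5b is ~ exp(-37.5), i.e. nil). Using
# one rule on both sides keeps generator and fit exactly consistent while
# avoiding an adaptive tail search inside the objective function.
build_fit_dist <- function(b, rL) {
  distance_distribution("ideal_chain_shifted", b = b, rL = rL,
                        rR = rL + 5 * b)
}

#' Model prediction for a set of conditions
#'
#' Builds the shifted ideal-chain distribution from \code{(b, rL)}, sets
#' \code{D = D_ref * d_scale} per condition, and evaluates the closed-form
#' effective distance. The static and dynamic limits are computed once per
#' distinct \code{(R0, tau-independent)} group, so a full multi-condition
#' prediction costs a handful of quadratures.
#'
#' @param params named list or vector with \code{D_ref} (A^2/ns),
#'   \code{b} (A) and \code{rL} (A).
#' @param conditions a data frame from [conditions_table()] (or the
#'   observation table, which contains the same columns).
#' @param coeffs calibration polynomials.
#' @return predicted effective distances, A (one per condition row).
#' @export
predict_reff <- function(params, conditions,
                         coeffs = published_coefficients()) {
  params <- as.list(params)
  dist <- build_fit_dist(params$b, params$rL)
  R <- dynamic_limit_R(dist)
  out <- numeric(nrow(conditions))
  for (R0 in unique(conditions$r0_angstrom)) {
    idx <- conditions$r0_angstrom == R0
    L <- static_limit_L(dist, R0)
    if (!(L > R)) stop("degenerate amplitude: L <= R")
    pm <- evaluate_polynomials(coeffs, R0 / params$rL)
    X <- sqrt(params$D_ref * conditions$d_scale[idx] *
                conditions$tau_d_ns[idx]) / R0
    di <- hsje_sigmoid(X, pm$X0, pm$M)
    out[idx] <- di * (R - L) + L
  }
  out
}

#' Global fit of chain structure and dynamics
#'
#' Bounded nonlinear least squares of the closed-form model to a
#' multi-condition table of effective distances, minimizing the
#' 1/sigma^2-weighted sum of squared residuals over \code{D_ref}, the
#' chain width \code{b}, and optionally the contact distance \code{rL}.
#' Positive parameters are optimized on the log scale; multiple
#' deterministic random starts guard against local minima.
#'
#' @param observations data frame with columns \code{tau_d_ns},
#'   \code{r0_angstrom}, \code{d_scale}, \code{reff_angstrom},
#'   \code{sigma_angstrom} (or \code{i_da}, \code{i_d} instead of
#'   \code{reff_angstrom}).
#' @param model0 list with start values \code{D_ref, b, rL}, a character
#'   vector \code{free} naming the free parameters (subset of
#'   \code{c("D_ref", "b", "rL")}), and optionally \code{bounds}, a named
#'   list of \code{c(lower, upper)} pairs.
#' @param coeffs calibration polynomials.
#' @param starts number of random starts (first start is \code{model0}
#'   itself).
#' @param seed integer seed for the start jitter.
#' @return a \code{dfret_fit_result}: estimates, SSR, residuals,
#'   approximate standard errors, Jacobian condition number, and the
#'   per-start log.
#' @export
fit_global <- function(observations, model0,
                       coeffs = published_coefficients(),
                       starts = 8L, seed = 1L) {
  obs <- as.data.frame(observations)
  if (is.null(obs$reff_angstrom)) {
    if (is.null(obs$i_da) || is.null(obs$i_d))
      stop("observations need 'reff_angstrom' or both 'i_da' and 'i_d'")
    obs$reff_angstrom <- reff_from_intensity(obs$i_da, obs$i_d,
                                             obs$r0_angstrom)
  }
  if (is.null(obs$sigma_angstrom)) obs$sigma_angstrom <- 1
  stopifnot(all(obs$reff_angstrom > 0), all(obs$sigma_angstrom > 0))

  free <- model0$free
  if (is.null(free)) free <- c("D_ref", "b")
  stopifnot(all(free %in% c("D_ref", "b", "rL")), length(free) >= 1L)
  if (nrow(obs) < length(free))
    stop("fewer observations than free parameters")
  J_vals <- obs$d_scale * obs$tau_d_ns / obs$r0_angstrom^2
  if ("D_ref" %in% free &&
      diff(range(J_vals)) < 1e-10 * max(J_vals))
    stop("conditions do not vary the augmented diffusion coefficient: ",
         "D_ref is unidentifiable")

  default_bounds <- list(D_ref = c(1e-6, 1e7),
                         b = c(2 * coeffs$validity$R0_range[1L] * 0.5,
                               2 * coeffs$validity$R0_range[2L] * 2),
                         rL = c(coeffs$validity$rL_range[1L],
                                coeffs$validity$rL_range[2L]))
  bounds <- utils::modifyList(default_bounds,
                              if (is.null(model0$bounds)) list()
                              else model0$bounds)

  # log transform for the scale parameters, identity for rL
  trans <- function(p, nm) if (nm == "rL") p else log(p)
  untrans <- function(p, nm) if (nm == "rL") p else exp(p)
  full <- function(theta) {
    p <- list(D_ref = model0$D_ref, b = model0$b, rL = model0$rL)
    for (k in seq_along(free)) p[[free[k]]] <- untrans(theta[k], free[k])
    p
  }
  wts <- 1 / obs$sigma_angstrom^2
  resid_fun <- function(theta) {
    p <- full(theta)
    pred <- tryCatch(predict_reff(p, obs, coeffs),
                     error = function(e) rep(NA_real_, nrow(obs)))
    obs$reff_angstrom - pred
  }
  obj <- function(theta) {
    r <- resid_fun(theta)
    if (any(!is.finite(r))) return(1e12)
    sum(wts * r^2)
  }
  lower <- vapply(free, function(nm) trans(bounds[[nm]][1L], nm), 0)
  upper <- vapply(free, function(nm) trans(bounds[[nm]][2L], nm), 0)
  theta0 <- vapply(free, function(nm) trans(model0[[nm]], nm), 0)

  set.seed(seed)
  start_list <- c(list(theta0), lapply(seq_len(max(0L, starts - 1L)),
    function(i) pmin(pmax(theta0 + stats::rnorm(length(theta0), 0, 0.3),
                          lower), upper)))
  runs <- lapply(start_list, function(th) {
    o <- stats::optim(th, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e4, maxit = 500L))
    list(par = o$par, ssr = o$value, convergence = o$convergence)
  })
  ssrs <- vapply(runs, `[[`, 0, "ssr")
  best <- runs[[which.min(ssrs)]]
  est <- full(best$par)

  # approximate standard errors and identifiability diagnostics from the
  # weighted Jacobian at the optimum
  eps <- 1e-6
  Jm <- vapply(seq_along(free), function(k) {
    tp <- best$par; tp[k] <- tp[k] + eps
    (resid_fun(tp) - resid_fun(best$par)) / eps
  }, numeric(nrow(obs)))
  Jw <- sqrt(wts) * Jm
  JtJ <- crossprod(Jw)
  cond <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  dof <- max(1L, nrow(obs) - length(free))
  s2 <- best$ssr / dof
  cov_theta <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  se <- if (is.null(cov_theta)) rep(NA_real_, length(free)) else {
    se_theta <- sqrt(pmax(0, diag(cov_theta)))
    # delta method back to the natural scale for log-parameters
    vapply(seq_along(free), function(k) {
      if (free[k] == "rL") se_theta[k]
      else se_theta[k] * est[[free[k]]]
    }, 0)
  }
  names(se) <- free
  residuals <- resid_fun(best$par)

  structure(list(estimates = est, free = free, se = se,
                 ssr = best$ssr, residuals = residuals,
                 jacobian_condition = cond,
                 convergence = best$convergence,
                 n_obs = nrow(obs),
                 starts = data.frame(
                   start = seq_along(runs), ssr = ssrs,
                   convergence = vapply(runs, `[[`, 0L, "convergence"))),
            class = "dfret_fit_result")
}

#' @export
print.dfret_fit_result <- function(x, ...) {
  cat("<dfret_fit_result>\n")
  for (nm in c("D_ref", "b", "rL")) {
    tag <- if (nm %in% x$free)
      sprintf(" (free, se %.3g)", x$se[[nm]]) else " (fixed)"
    unit <- if (nm == "D_ref") "A^2/ns" else "A"
    cat(sprintf("  %-5s = %.5g %s%s\n", nm, x$estimates[[nm]], unit, tag))
  }
  cat(sprintf("  SSR = %.6g over %d observations; Jacobian condition %.3g\n",
              x$ssr, x$n_obs, x$jacobian_condition))
  invisible(x)
}
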