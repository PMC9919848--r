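#' Validity check against the calibration ranges
#'
#' The calibration polynomials are only trustworthy inside the grid they
#' were fitted on. Flags R0 or rL outside the validity ranges and ratios
#' \code{R0/rL} below the ratio constraint.
#'
#' @param photo a \code{dfret_photo}.
#' @param rL contact distance, A.
#' @param coeffs a \code{dfret_poly_model}.
#' @param strict raise an error on violation instead of warning.
#' @return invisibly, a list \code{(ok, flags)}.
#' @export
validity_check <- function(photo, rL, coeffs = published_coefficients(),
                           strict = FALSE) {
  v <- coeffs$validity
  flags <- character(0)
  if (photo$R0 < v$R0_range[1L] || photo$R0 > v$R0_range[2L])
    flags <- c(flags, sprintf("R0 = %g A outside [%g, %g] A", photo$R0,
                              v$R0_range[1L], v$R0_range[2L]))
  if (rL < v$rL_range[1L] || rL > v$rL_range[2L])
    flags <- c(flags, sprintf("rL = %g A outside [%g, %g] A", rL,
                              v$rL_range[1L], v$rL_range[2L]))
  ratio <- photo$R0 / rL
  if (ratio < v$ratio_min - 1e-9)
    flags <- c(flags, sprintf("R0/rL = %g below ratio constraint %g",
                              ratio, v$ratio_min))
  ok <- length(flags) == 0L
  if (!ok) {
    msg <- paste("outside calibration validity:",
                 paste(flags, collapse = "; "))
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(list(ok = ok, flags = flags))
}

#' Closed-form effective distance (no PDE solve)
#'
#' Evaluates the closed analytical surrogate of the population equation.
#' The eight constituents, computed in order:
#' \enumerate{
#'   \item static limit \code{L} (quadrature),
#'   \item dynamic limit \code{R} (quadrature),
#'   \item ratio \code{rho = R0/rL},
#'   \item \code{X = sqrt(D tau_D)/R0},
#'   \item \code{X0(rho)} from the calibration polynomial,
#'   \item \code{M(rho)} from the calibration polynomial,
#'   \item \code{DI = (X/X0)^M / (1 + (X/X0)^M)},
#'   \item \code{Reff = DI (R - L) + L}.
#' }
#' Cost is two adaptive quadratures plus arithmetic.
#'
#' @param dist a normalized \code{dfret_dist}.
#' @param photo a \code{dfret_photo}.
#' @param D diffusion coefficient, A^2/ns.
#' @param coeffs calibration polynomials (default: built-in).
#' @param strict validity handling: \code{TRUE} errors outside the
#'   calibrated ranges, \code{FALSE} warns, \code{NA} stays silent.
#' @param details return all constituents instead of just Reff.
#' @return effective distance in A, or (with \code{details = TRUE}) a
#'   list \code{(L, R, rho, X, X0, M, DI, R_eff)}.
#' @export
hsje_reff <- function(dist, photo, D, coeffs = published_coefficients(),
                      strict = FALSE, details = FALSE) {
  stopifnot(inherits(dist, "dfret_dist"), inherits(photo, "dfret_photo"))
  if (!is.na(strict))
    validity_check(photo, dist$rL, coeffs, strict = strict)
  L <- static_limit_L(dist, photo$R0)
  R <- dynamic_limit_R(dist)
  if (!(L > R)) stop("degenerate amplitude: L <= R")
  rho <- photo$R0 / dist$rL
  X <- augmented_J(D, photo$tau_D, photo$R0)$X
  pm <- evaluate_polynomials(coeffs, rho)
  di <- hsje_sigmoid(X, pm$X0, pm$M)
  reff <- di * (R - L) + L
  if (details)
    list(L = L, R = R, rho = rho, X = X, X0 = pm$X0, M = pm$M,
         DI = di, R_eff = reff)
  else reff
}

# The calibrated sigmoid, written to be exact at both endpoints
# (DI(0) = 0, DI(Inf) = 1) without overflow.
hsje_sigmoid <- function(X, X0, M) {
  ifelse(X <= 0, 0, stats::plogis(M * (log(X) - log(X0))))
}

#' Closed-form diffusion influence and predicted observables
#'
#' \code{hsje_di()} returns the sigmoid value \code{DI} in \code{[0, 1]};
#' \code{hsje_predict_observables()} converts the closed-form effective
#' distance into the full set of transfer observables (efficiency,
#' effective FRET rate, donor decay rate with acceptor).
#'
#' @inheritParams hsje_reff
#' @return \code{hsje_di()}: DI in \code{[0, 1]}.
#'   \code{hsje_predict_observables()}: a list
#'   \code{(R_eff, E, k_FRET, k_DA, DI)}.
#' @export
hsje_di <- function(dist, photo, D, coeffs = published_coefficients(),
                    strict = FALSE) {
  hsje_reff(dist, photo, D, coeffs, strict, details = TRUE)$DI
}

#' @rdname hsje_di
#' @export
hsje_predict_observables <- function(dist, photo, D,
                                     coeffs = published_coefficients(),
                                     strict = FALSE) {
  d <- hsje_reff(dist, photo, D, coeffs, strict, details = TRUE)
  E <- reff_to_efficiency(d$R_eff, photo$R0)
  k_FRET <- photo$k_D * E / (1 - E)
  list(R_eff = d$R_eff, E = E, k_FRET = k_FRET,
       k_DA = photo$k_D + k_FRET, DI = d$DI)
}
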