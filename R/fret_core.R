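#' Donor photophysics
#'
#' Bundle of the photophysical constants of a FRET pair: donor lifetime
#' \code{tau_D} (ns), Foerster radius \code{R0} (A), and the derived donor
#' decay rate \code{k_D = 1/tau_D} (1/ns). Optionally the radiative and
#' non-radiative components \code{k_rad + k_nrad = k_D} may be supplied.
#'
#' @param tau_D donor lifetime in the donor-only construct, ns.
#' @param R0 Foerster radius, A.
#' @param k_rad,k_nrad optional rate components, 1/ns.
#' @return an object of class \code{dfret_photo}.
#' @export
photophysics <- function(tau_D, R0, k_rad = NULL, k_nrad = NULL) {
  if (!is.finite(tau_D) || tau_D <= 0) stop("'tau_D' must be positive (ns)")
  if (!is.finite(R0) || R0 <= 0) stop("'R0' must be positive (A)")
  k_D <- 1 / tau_D
  if (!is.null(k_rad) || !is.null(k_nrad)) {
    if (is.null(k_rad) || is.null(k_nrad))
      stop("supply both 'k_rad' and 'k_nrad' or neither")
    if (abs(k_rad + k_nrad - k_D) > 1e-9)
      stop("k_rad + k_nrad must equal k_D = 1/tau_D")
  }
  structure(list(tau_D = tau_D, R0 = R0, k_D = k_D,
                 k_rad = k_rad, k_nrad = k_nrad),
            class = "dfret_photo")
}

#' @export
print.dfret_photo <- function(x, ...) {
  cat(sprintf("<dfret_photo> tau_D = %g ns, R0 = %g A, k_D = %g 1/ns\n",
              x$tau_D, x$R0, x$k_D))
  invisible(x)
}

#' Foerster transfer rate at a fixed distance
#'
#' \code{k_T(r) = k_D (R0/r)^6}.
#'
#' @param photo a \code{dfret_photo}.
#' @param r donor--acceptor distance, A (positive).
#' @return rate in 1/ns.
#' @export
forster_rate <- function(photo, r) {
  if (any(r <= 0)) stop("distance must be positive")
  photo$k_D * (photo$R0 / r)^6
}

#' Effective FRET rate from measured decay rates
#'
#' \code{k_FRET = k_DA - k_D}, the excess decay rate in the donor-acceptor
#' construct over the donor-only construct.
#'
#' @param k_DA donor decay rate with acceptor, 1/ns.
#' @param k_D donor-only decay rate, 1/ns.
#' @return rate in 1/ns.
#' @export
kfret_from_rates <- function(k_DA, k_D) {
  if (any(k_D <= 0)) stop("'k_D' must be positive")
  if (any(k_DA < k_D))
    stop("k_DA < k_D: negative transfer rate, inconsistent inputs")
  k_DA - k_D
}

#' Effective distance from the effective FRET rate
#'
#' Inverts Foerster's law for the single distance reproducing the observed
#' ensemble rate: \code{R_eff = R0 (k_D / k_FRET)^(1/6)}.
#'
#' @param k_FRET effective transfer rate, 1/ns (positive).
#' @param photo a \code{dfret_photo}.
#' @return effective distance in A.
#' @export
reff_from_kfret <- function(k_FRET, photo) {
  if (any(k_FRET <= 0))
    stop("k_FRET <= 0: effective distance undefined (no transfer)")
  photo$R0 * (photo$k_D / k_FRET)^(1 / 6)
}

#' Convert between transfer efficiency and effective distance
#'
#' \code{R_eff = R0 ((1 - E)/E)^(1/6)} and its exact inverse
#' \code{E = 1 / (1 + (R_eff/R0)^6)}.
#'
#' @param E transfer efficiency in (0, 1).
#' @param R_eff effective distance, A.
#' @param R0 Foerster radius, A.
#' @return distance in A, or efficiency.
#' @export
efficiency_to_reff <- function(E, R0) {
  if (any(E <= 0)) stop("E <= 0: no transfer, effective distance undefined")
  if (any(E >= 1)) stop("E >= 1: effective distance undefined")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' @rdname efficiency_to_reff
#' @export
reff_to_efficiency <- function(R_eff, R0) {
  if (any(R_eff <= 0)) stop("R_eff must be positive")
  1 / (1 + (R_eff / R0)^6)
}

#' Static (no-diffusion) limit of the effective distance
#'
#' For a frozen ensemble the transfer efficiency is the density-weighted
#' average of the per-distance Foerster efficiency,
#' \code{E_static = int p(r) R0^6/(r^6 + R0^6) dr}; the static limit
#' \code{L} is the effective distance of that efficiency,
#' \code{L = R0 ((1 - S)^-1 - 1)^(1/6)} with
#' \code{S = int p(r) r^6/(r^6 + R0^6) dr}.
#'
#' @param dist a normalized \code{dfret_dist} with \code{rL > 0}.
#' @param R0 Foerster radius, A.
#' @return \code{L} in A.
#' @export
static_limit_L <- function(dist, R0) {
  stopifnot(inherits(dist, "dfret_dist"))
  S <- stats::integrate(function(r)
    evaluate_pdf(dist, r) * r^6 / (r^6 + R0^6),
    dist$rL, dist$rR, abs.tol = 1e-10, rel.tol = 1e-10,
    subdivisions = 500L)$value
  if (S >= 1 - 1e-14)
    stop("static efficiency is zero: effective distance undefined")
  R0 * (1 / (1 - S) - 1)^(1 / 6)
}

#' Dynamic (infinite-diffusion) limit of the effective distance
#'
#' \code{R = <r^-6>^(-1/6)}: in the fast-diffusion limit the chain samples
#' its whole distance distribution within the donor lifetime and the
#' ensemble transfers with the distribution-averaged rate.
#'
#' @param dist a normalized \code{dfret_dist} with \code{rL > 0}.
#' @return \code{R} in A.
#' @export
dynamic_limit_R <- function(dist) {
  inverse_sixth_moment(dist)^(-1 / 6)
}

#' Augmented diffusion coefficient
#'
#' \code{J = D tau_D / R0^2} is dimensionless for D in A^2/ns, tau_D in ns
#' and R0 in A; \code{X = sqrt(J)} is the natural abscissa of
#' diffusion-influence profiles.
#'
#' @param D diffusion coefficient, A^2/ns.
#' @param tau_D donor lifetime, ns.
#' @param R0 Foerster radius, A.
#' @return a list with \code{J} and \code{X}.
#' @export
augmented_J <- function(D, tau_D, R0) {
  if (any(tau_D <= 0) || any(R0 <= 0) || any(D < 0))
    stop("D must be >= 0 and tau_D, R0 > 0")
  J <- D * tau_D / R0^2
  list(J = J, X = sqrt(J))
}

#' Diffusion influence
#'
#' Normalized position of the effective distance between the static limit
#' \code{L} and dynamic limit \code{R}:
#' \code{DI = (R_eff - L) / (R - L)}, 0 at the static and 1 at the dynamic
#' limit. Values within \code{clip} outside \code{[0, 1]} (numerical
#' overshoot of a converged solve) are clipped; values further outside
#' raise an error.
#'
#' @param R_eff effective distance(s), A.
#' @param L,R static and dynamic limits, A (\code{L > R}).
#' @param clip clipping window, default \code{1e-3}.
#' @param min_amplitude smallest admissible \code{L - R}; narrower
#'   distributions give an ill-conditioned normalization.
#' @return DI value(s) in \code{[0, 1]}.
#' @export
diffusion_influence <- function(R_eff, L, R, clip = 1e-3,
                                min_amplitude = 1e-6) {
  if (!(L > R)) stop("need L > R for a non-degenerate amplitude")
  if ((L - R) < min_amplitude)
    stop("profile amplitude L - R = ", signif(L - R, 3),
         " A below threshold; diffusion influence is ill-conditioned")
  di <- (R_eff - L) / (R - L)
  if (any(di < -clip) || any(di > 1 + clip))
    stop("R_eff outside [R, L] beyond the numerical clipping window")
  pmin(pmax(di, 0), 1)
}
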