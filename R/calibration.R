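#' Calibration grid specification
#'
#' The sigmoid parameters \code{(X0, M)} depend on the Foerster radius and
#' contact distance only through the ratio \code{rho = R0/rL}. They are
#' calibrated on a grid of \code{(R0, rL)} combinations covering the
#' short-distance FRET regime: R0 = 9--15 A by 1 A, rL = 1.5--5 A by
#' 0.5 A (56 combinations). Each combination uses the shifted ideal-chain
#' distribution with \code{b = b_rule * R0} (default 2, broad enough for a
#' large profile amplitude and hence well-conditioned sigmoids) and a
#' donor lifetime of 100 ns.
#'
#' @param R0_values Foerster radii, A.
#' @param rL_values contact distances, A.
#' @param b_rule multiplier b = b_rule * R0 for the ideal-chain width.
#' @param tau_D donor lifetime, ns.
#' @param D_values diffusion-coefficient grid, A^2/ns.
#' @param ratio_min smallest R0/rL admitted to the polynomial fit
#'   (inclusive).
#' @param n_space spatial resolution per solve.
#' @return a \code{dfret_grid_spec}.
#' @export
grid_spec <- function(R0_values = seq(9, 15, by = 1),
                      rL_values = seq(1.5, 5, by = 0.5),
                      b_rule = 2, tau_D = 100,
                      D_values = default_D_grid(),
                      ratio_min = 3, n_space = 800L) {
  stopifnot(all(R0_values > 0), all(rL_values > 0), b_rule > 0,
            tau_D > 0, all(D_values > 0))
  structure(list(R0_values = R0_values, rL_values = rL_values,
                 b_rule = b_rule, tau_D = tau_D, D_values = D_values,
                 ratio_min = ratio_min, n_space = as.integer(n_space)),
            class = "dfret_grid_spec")
}

#' Run the sigmoid calibration grid
#'
#' For each \code{(R0, rL)} combination: build the shifted ideal-chain
#' distribution with \code{b = b_rule * R0}, solve the population equation
#' over the diffusion grid, normalize by the closed-form limits, and fit
#' the sigmoid. Per-combination failures are recorded in the table, not
#' fatal.
#'
#' @param spec a \code{dfret_grid_spec}.
#' @param verbose print progress.
#' @return a \code{dfret_coef_table}: data frame with columns
#'   \code{R0, rL, ratio, X0, M, rms, asymmetry, error}.
#' @export
run_grid <- function(spec = grid_spec(), verbose = FALSE) {
  stopifnot(inherits(spec, "dfret_grid_spec"))
  combos <- expand.grid(rL = spec$rL_values, R0 = spec$R0_values,
                        KEEP.OUT.ATTRS = FALSE)[, c("R0", "rL")]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    R0 <- combos$R0[i]; rL <- combos$rL[i]
    if (verbose) message(sprintf("grid %d/%d: R0=%g rL=%g",
                                 i, nrow(combos), R0, rL))
    out <- tryCatch({
      dist <- distance_distribution("ideal_chain_shifted",
                                    b = spec$b_rule * R0, rL = rL)
      photo <- photophysics(tau_D = spec$tau_D, R0 = R0)
      fit <- profile_and_fit(dist, photo, D_values = spec$D_values,
                             n_space = spec$n_space)
      data.frame(R0 = R0, rL = rL, ratio = R0 / rL,
                 X0 = fit$X0, M = fit$M, rms = fit$rms_residual,
                 asymmetry = fit$asymmetry_diagnostic,
                 error = NA_character_)
    }, error = function(e)
      data.frame(R0 = R0, rL = rL, ratio = R0 / rL,
                 X0 = NA_real_, M = NA_real_, rms = NA_real_,
                 asymmetry = NA_real_, error = conditionMessage(e)))
    out
  })
  tab <- do.call(rbind, rows)
  structure(tab, spec = spec,
            class = c("dfret_coef_table", "data.frame"))
}

#' Fit the calibration polynomials X0(rho), M(rho)
#'
#' Ordinary least squares of the fitted sigmoid parameters against
#' \code{(1, rho, rho^2)}, \code{rho = R0/rL}, over grid rows with
#' \code{rho >= ratio_min}.
#'
#' @param table a \code{dfret_coef_table} from [run_grid()] (or any data
#'   frame with columns \code{ratio, X0, M}).
#' @param ratio_min smallest admitted ratio (inclusive); defaults to the
#'   table's grid spec value, else 3.
#' @param validity optional list recording the validity ranges.
#' @return a \code{dfret_poly_model}.
#' @export
fit_polynomials <- function(table, ratio_min = NULL, validity = NULL) {
  spec <- attr(table, "spec")
  if (is.null(ratio_min))
    ratio_min <- if (!is.null(spec)) spec$ratio_min else 3
  df <- as.data.frame(table)
  df <- df[is.finite(df$X0) & df$ratio >= ratio_min - 1e-9, ]
  if (length(unique(round(df$ratio, 9))) < 3L)
    stop("need at least 3 distinct R0/rL ratios above ratio_min")
  fx <- stats::lm(X0 ~ ratio + I(ratio^2), data = df)
  fm <- stats::lm(M ~ ratio + I(ratio^2), data = df)
  cx <- unname(stats::coef(fx)); cm <- unname(stats::coef(fm))
  if (any(!is.finite(c(cx, cm)))) stop("rank-deficient polynomial fit")
  if (is.null(validity)) {
    validity <- list(
      R0_range = if (!is.null(spec)) range(spec$R0_values) else c(9, 15),
      rL_range = if (!is.null(spec)) range(spec$rL_values) else c(1.5, 5),
      ratio_min = ratio_min)
  }
  polynomial_model(a0 = cx[1L], a1 = cx[2L], a2 = cx[3L],
                   b0 = cm[1L], b1 = cm[2L], b2 = cm[3L],
                   validity = validity,
                   source = "refit",
                   rms = c(X0 = sqrt(mean(stats::resid(fx)^2)),
                           M = sqrt(mean(stats::resid(fm)^2))))
}

#' Second-degree calibration polynomials
#'
#' Container for \code{X0(rho) = a0 + a1 rho + a2 rho^2} and
#' \code{M(rho) = b0 + b1 rho + b2 rho^2}, \code{rho = R0/rL}, with their
#' validity ranges.
#'
#' @param a0,a1,a2 X0 polynomial coefficients.
#' @param b0,b1,b2 M polynomial coefficients.
#' @param validity list with \code{R0_range}, \code{rL_range},
#'   \code{ratio_min}.
#' @param source provenance tag.
#' @param rms optional fit residuals.
#' @return a \code{dfret_poly_model}.
#' @export
polynomial_model <- function(a0, a1, a2, b0, b1, b2,
                             validity = list(R0_range = c(9, 15),
                                             rL_range = c(1.5, 5),
                                             ratio_min = 3),
                             source = "user", rms = NULL) {
  structure(list(a = c(a0 = a0, a1 = a1, a2 = a2),
                 b = c(b0 = b0, b1 = b1, b2 = b2),
                 validity = validity, source = source, rms = rms),
            class = "dfret_poly_model")
}

#' @export
print.dfret_poly_model <- function(x, ...) {
  cat("<dfret_poly_model> (", x$source, ")\n", sep = "")
  cat(sprintf("  X0(rho) = %+g %+g rho %+g rho^2\n",
              x$a[1L], x$a[2L], x$a[3L]))
  cat(sprintf("  M(rho)  = %+g %+g rho %+g rho^2\n",
              x$b[1L], x$b[2L], x$b[3L]))
  cat(sprintf("  valid: R0 in [%g, %g] A, rL in [%g, %g] A, R0/rL >= %g\n",
              x$validity$R0_range[1L], x$validity$R0_range[2L],
              x$validity$rL_range[1L], x$validity$rL_range[2L],
              x$validity$ratio_min))
  invisible(x)
}

#' Evaluate the calibration polynomials
#'
#' @param coeffs a \code{dfret_poly_model}.
#' @param ratio rho = R0/rL value(s).
#' @return a list with vectors \code{X0} and \code{M}.
#' @export
evaluate_polynomials <- function(coeffs, ratio) {
  stopifnot(inherits(coeffs, "dfret_poly_model"))
  list(X0 = coeffs$a[[1L]] + coeffs$a[[2L]] * ratio +
         coeffs$a[[3L]] * ratio^2,
       M = coeffs$b[[1L]] + coeffs$b[[2L]] * ratio +
         coeffs$b[[3L]] * ratio^2)
}

#' Built-in calibration coefficients
#'
#' The reference second-degree polynomial coefficients for
#' \code{X0(rho)} and \code{M(rho)}, calibrated on the 56-combination
#' grid with the shifted ideal-chain model and \code{b = 2 R0}. Valid for
#' R0 = 9--15 A, rL = 1.5--5 A, R0/rL > 3.
#'
#' @return a \code{dfret_poly_model}.
#' @export
published_coefficients <- function() {
  polynomial_model(a0 = -0.023191, a1 = 0.333543, a2 = -0.008843,
                   b0 = 2.262606, b1 = -0.185375, b2 = 0.008271,
                   source = "published")
}

#' Export helpers for calibration results
#'
#' @param table a \code{dfret_coef_table}.
#' @param file path.
#' @export
write_coef_table_csv <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}

#' @param coeffs a \code{dfret_poly_model}.
#' @rdname write_coef_table_csv
#' @export
write_poly_model_json <- function(coeffs, file) {
  jsonlite::write_json(list(a = as.list(coeffs$a), b = as.list(coeffs$b),
                            validity = coeffs$validity,
                            source = coeffs$source),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @param file path to a JSON written by [write_poly_model_json()].
#' @rdname write_coef_table_csv
#' @export
read_poly_model_json <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  polynomial_model(j$a$a0, j$a$a1, j$a$a2, j$b$b0, j$b$b1, j$b$b2,
                   validity = j$validity, source = j$source)
}
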