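#' Axial/equatorial equilibrium constant from peak integrals
#'
#' K for the equatorial-to-axial transition is the integral ratio of the
#' best-isolated peaks of each conformer, after subtracting any co-resonating
#' impurity from the nominated peak.
#'
#' @param ax_integral,eq_integral Peak areas (arbitrary, same scale).
#' @param impurity_correction Area subtracted from the peak named in
#'   `correct` (default 0).
#' @param correct Which peak carries the impurity (default `"eq"`).
#' @return List with `k_ax_eq` (= ax/eq) and `fraction_axial`
#'   (= K/(1+K), proportion in `[0, 1]`).
#' @examples
#' conformer_ratio(1, 5, impurity_correction = 1)  # K = 0.25
#' @export
conformer_ratio <- function(ax_integral, eq_integral, impurity_correction = 0,
                            correct = c("eq", "ax")) {
  correct <- match.arg(correct)
  ax <- ax_integral - if (correct == "ax") impurity_correction else 0
  eq <- eq_integral - if (correct == "eq") impurity_correction else 0
  if (ax <= 0 || eq <= 0) {
    stop("corrected integrals must be positive", call. = FALSE)
  }
  k <- ax / eq
  list(k_ax_eq = k, fraction_axial = k / (1 + k))
}

#' Build a conformer equilibrium series
#'
#' @param temperature Kelvin.
#' @param k_ax_eq Equilibrium constants (> 0), one per row.
#' @param replicate Replicate labels (pooled, not averaged, by
#'   [vant_hoff_fit()]).
#' @param mg_equiv,ph_star Optional condition metadata.
#' @return A `conformer_series` data.frame.
#' @export
conformer_series <- function(temperature, k_ax_eq, replicate = 1L,
                             mg_equiv = NA, ph_star = NA) {
  if (any(k_ax_eq <= 0)) stop("k_ax_eq must be positive", call. = FALSE)
  if (any(temperature <= 0)) stop("temperatures must be Kelvin (> 0)",
                                  call. = FALSE)
  df <- data.frame(temperature = temperature, k_ax_eq = k_ax_eq,
                   replicate = replicate)
  attr(df, "mg_equiv") <- mg_equiv
  attr(df, "ph_star") <- ph_star
  class(df) <- c("conformer_series", "data.frame")
  df
}

#' Van't Hoff regression of a conformer series
#'
#' Ordinary least squares of \eqn{\ln K} on \eqn{1/T} over all points
#' (replicates pooled into one regression).  Then
#' \eqn{\Delta H^0 = -\mathrm{slope} \cdot R} and
#' \eqn{\Delta S^0 = \mathrm{intercept} \cdot R} with
#' R = 1.987204e-3 kcal/(mol K).  Standard errors are the regression standard
#' errors propagated through the same factors.
#'
#' @param series A [conformer_series()] (or data.frame with `temperature`
#'   and `k_ax_eq`).
#' @return A `thermo_params`: `delta_h` (kcal/mol), `delta_s`
#'   (kcal/(mol K)), `se_delta_h`, `se_delta_s`, `r_squared`, `n`,
#'   `r_gas`, and `per_replicate` diagnostics when replicates are present.
#' @export
vant_hoff_fit <- function(series) {
  t <- series$temperature
  k <- series$k_ax_eq
  if (length(unique(t)) < 3L) {
    stop("van't Hoff regression needs at least 3 distinct temperatures",
         call. = FALSE)
  }
  fit <- stats::lm(log(k) ~ I(1 / t))
  co <- summary(fit)$coefficients
  per_rep <- NULL
  if (!is.null(series$replicate) && length(unique(series$replicate)) > 1L) {
    per_rep <- lapply(split(seq_along(t), series$replicate), function(idx) {
      if (length(unique(t[idx])) < 3L) return(NULL)
      f <- stats::lm(log(k[idx]) ~ I(1 / t[idx]))
      c(delta_h = -unname(stats::coef(f)[2L]) * R_KCAL,
        delta_s = unname(stats::coef(f)[1L]) * R_KCAL)
    })
  }
  structure(
    list(delta_h = -co[2L, 1L] * R_KCAL, delta_s = co[1L, 1L] * R_KCAL,
         se_delta_h = co[2L, 2L] * R_KCAL, se_delta_s = co[1L, 2L] * R_KCAL,
         r_squared = summary(fit)$r.squared, n = length(t), r_gas = R_KCAL,
         per_replicate = per_rep),
    class = "thermo_params")
}

#' Construct thermodynamic parameters directly
#'
#' @param delta_h Kcal/mol.
#' @param delta_s Kcal/(mol K).
#' @param se_delta_h,se_delta_s Standard errors (>= 0), optional.
#' @return A `thermo_params`.
#' @export
thermo_params <- function(delta_h, delta_s, se_delta_h = 0, se_delta_s = 0) {
  if (se_delta_h < 0 || se_delta_s < 0) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  structure(list(delta_h = delta_h, delta_s = delta_s,
                 se_delta_h = se_delta_h, se_delta_s = se_delta_s,
                 r_squared = NA_real_, n = NA_integer_, r_gas = R_KCAL,
                 per_replicate = NULL),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> dH0 = %.3g +/- %.2g kcal/mol, dS0 = %.3g +/- %.2g kcal/(mol K)",
              x$delta_h, x$se_delta_h, x$delta_s, x$se_delta_s))
  if (is.finite(x$r_squared)) cat(sprintf(" (R2 = %.4f, n = %d)", x$r_squared, x$n))
  cat("\n")
  invisible(x)
}

#' Percent axial conformer at a temperature (Gibbs-Helmholtz)
#'
#' \eqn{\Delta G = \Delta H^0 - T \Delta S^0}, \eqn{K = e^{-\Delta G / RT}},
#' \eqn{f_{ax} = K/(1+K)}.  Returns the raw percentage; round for reporting
#' (e.g. 1.9 -> "2%").
#'
#' @param params A `thermo_params` (from [vant_hoff_fit()] or
#'   [thermo_params()]).
#' @param temperature Kelvin (> 0).  Both 310 and 310.15 K are sensible
#'   readings of "37 degC"; the caller chooses.
#' @return Percent axial conformer in (0, 100).
#' @examples
#' fraction_axial(thermo_params(-7.2, -0.025), 310)  # ~29
#' @export
fraction_axial <- function(params, temperature) {
  if (temperature <= 0) stop("temperature must be Kelvin (> 0)", call. = FALSE)
  dg <- params$delta_h - temperature * params$delta_s
  k <- exp(-dg / (R_KCAL * temperature))
  100 * k / (1 + k)
}

#' Convert apparent D2O pH* to pH
#'
#' Linear meter correction `pH = 0.929 * pH* + 0.42`.
#'
#' @param ph_star Apparent pH measured in D2O.
#' @return pH (unrounded; rounding is the caller's display choice).
#' @examples
#' ph_star_to_ph(7.5)  # 7.3875 -> "7.4"
#' @export
ph_star_to_ph <- function(ph_star) {
  0.929 * ph_star + 0.42
}
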