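#' Define an ITC injection protocol
#'
#' @param cell_conc Macromolecule concentration in the cell, mol/L.
#' @param syringe_conc Ligand concentration in the syringe, mol/L.
#' @param injection_volumes_ul Injection volumes, uL (default nineteen 2-uL
#'   steps).
#' @param cell_volume_ul Active cell volume V0, uL.  The instrument-defined
#'   active volume of a PEAQ-type cell (200 uL default); simulator and fitter
#'   share this object, so recovery only requires consistency.
#' @param temperature Kelvin (default 298.15, i.e. 25 degC).
#' @return An `itc_protocol` with cumulative injected volume per injection.
#' @export
itc_protocol <- function(cell_conc, syringe_conc,
                         injection_volumes_ul = rep(2, 19),
                         cell_volume_ul = 200, temperature = 298.15) {
  if (cell_conc <= 0 || syringe_conc <= 0) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (any(injection_volumes_ul <= 0) || cell_volume_ul <= 0) {
    stop("volumes must be positive", call. = FALSE)
  }
  structure(
    list(cell_conc = cell_conc, syringe_conc = syringe_conc,
         injection_volumes_ul = injection_volumes_ul,
         cumulative_volume_ul = cumsum(injection_volumes_ul),
         cell_volume_ul = cell_volume_ul, temperature = temperature),
    class = "itc_protocol")
}

#' One-site binding parameters
#'
#' Derived quantities use the 1 M standard state:
#' \eqn{\Delta G = RT \ln K_d}, \eqn{-T\Delta S = \Delta G - \Delta H}, so
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds identically.
#'
#' @param n Stoichiometry (sites per macromolecule).
#' @param k_d Dissociation constant, mol/L (> 0).
#' @param delta_h Binding enthalpy, kcal/mol of ligand.
#' @param dilution_offset Constant per-injection heat offset, kcal/mol
#'   (stands in for a blank titration).
#' @param temperature Kelvin used for the derived terms.
#' @return A `binding_params` with `delta_g` and `minus_t_delta_s`.
#' @export
binding_params <- function(n, k_d, delta_h, dilution_offset = 0,
                           temperature = 298.15) {
  if (k_d <= 0) stop("k_d must be positive", call. = FALSE)
  dg <- R_KCAL * temperature * log(k_d)
  structure(
    list(n = n, k_d = k_d, delta_h = delta_h,
         dilution_offset = dilution_offset, temperature = temperature,
         delta_g = dg, minus_t_delta_s = dg - delta_h),
    class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> n = %.3g, Kd = %.3g M, dH = %.3g, dG = %.3g, -TdS = %.3g kcal/mol (T = %.2f K)\n",
              x$n, x$k_d, x$delta_h, x$delta_g, x$minus_t_delta_s,
              x$temperature))
  if (!is.null(attr(x, "c_value"))) {
    cat(sprintf("  c = %.3g%s\n", attr(x, "c_value"),
                if (isTRUE(attr(x, "low_information"))) " (outside [1,1000]: low-information fit)" else ""))
  }
  invisible(x)
}

# Cell concentrations corrected for injection displacement (overfill cell:
# each injection expels mixed solution).  dv_cum in uL.
itc_displaced_concentrations <- function(protocol) {
  v0 <- protocol$cell_volume_ul
  dv <- protocol$cumulative_volume_ul
  list(m_t = protocol$cell_conc * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0)),
       x_t = protocol$syringe_conc * (dv / v0) / (1 + dv / (2 * v0)))
}

# Cumulative heat content (kcal) of the cell after each injection from the
# single-site Wiseman closed form.
itc_cumulative_heat <- function(protocol, params) {
  cc <- itc_displaced_concentrations(protocol)
  v0_l <- protocol$cell_volume_ul * 1e-6
  nm <- params$n * cc$m_t
  r <- cc$x_t / nm
  kd <- params$k_d / nm
  (nm * params$delta_h * v0_l / 2) *
    (1 + r + kd - sqrt((1 + r + kd)^2 - 4 * r))
}

#' Simulate a one-site ITC isotherm
#'
#' Per-injection heats follow the single-site (Wiseman) model with
#' injection-displacement corrections: cumulative heat from the binding
#' quadratic's closed form, differenced with the expelled-volume term
#' \eqn{\Delta Q_i = Q_i + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2} - Q_{i-1}},
#' normalized by moles of injectant, plus the dilution offset and optional
#' i.i.d. Gaussian noise.
#'
#' @param protocol An [itc_protocol()].
#' @param params A [binding_params()].
#' @param noise_sd Gaussian noise on the normalized heats, kcal/mol.
#' @param seed Optional integer for reproducible noise.
#' @return An `isotherm` data.frame: `injection`, `volume_ul`,
#'   `molar_ratio` (X_t/M_t), `heat_kcal_per_mol`.
#' @export
simulate_isotherm <- function(protocol, params, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "itc_protocol"), inherits(params, "binding_params"))
  q <- itc_cumulative_heat(protocol, params)
  cc <- itc_displaced_concentrations(protocol)
  v0 <- protocol$cell_volume_ul
  dv <- protocol$injection_volumes_ul
  q_prev <- c(0, q[-length(q)])
  dq <- q + (dv / v0) * (q + q_prev) / 2 - q_prev
  mol_inj <- protocol$syringe_conc * dv * 1e-6
  ndh <- dq / mol_inj + params$dilution_offset
  if (noise_sd > 0) {
    ndh <- ndh + with_seed(seed, stats::rnorm(length(ndh), 0, noise_sd))
  }
  structure(
    data.frame(injection = seq_along(dv), volume_ul = dv,
               molar_ratio = cc$x_t / cc$m_t, heat_kcal_per_mol = ndh),
    class = c("isotherm", "data.frame"))
}

#' Fit the one-site model to an isotherm
#'
#' Least squares over (n, log10 Kd, dH, dilution offset) with [stats::nlminb()]
#' and the same forward model as [simulate_isotherm()].  The Wiseman c-value
#' \eqn{c = n M_t / K_d} is attached; values outside `[1, 1000]` flag a
#' low-information isotherm (the fit is still returned).
#'
#' @param isotherm An `isotherm` (needs `heat_kcal_per_mol`).
#' @param protocol The matching [itc_protocol()].
#' @param fix_n Fix the stoichiometry at this value instead of floating it
#'   (default `NULL`: floated).
#' @param discard_first Drop injection 1 before fitting (common practice for
#'   diffusion-corrupted first injections; default off).
#' @param weights Optional per-injection weights.
#' @return A [binding_params()] with attributes `sd` (named parameter standard
#'   deviations), `c_value`, `low_information`, `converged`, `rmse`,
#'   `kd_undetermined` (degenerate flat isotherms).
#' @export
fit_one_site <- function(isotherm, protocol, fix_n = NULL,
                         discard_first = FALSE, weights = NULL) {
  y_all <- isotherm$heat_kcal_per_mol
  keep <- seq_along(y_all)
  if (discard_first) keep <- keep[-1L]
  if (length(keep) < 5L) stop("need at least 5 injections", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y_all))
  w <- weights[keep]
  y <- y_all[keep]

  predict_heats <- function(n, kd, dh, offset) {
    p <- binding_params(n, kd, dh, offset, protocol$temperature)
    simulate_isotherm(protocol, p)$heat_kcal_per_mol[keep]
  }
  # degenerate input: no heat signal at all
  if (stats::sd(y) < 1e-12) {
    out <- binding_params(if (is.null(fix_n)) 1 else fix_n, 1e-6,
                          delta_h = 0, dilution_offset = mean(y),
                          temperature = protocol$temperature)
    attr(out, "kd_undetermined") <- TRUE
    attr(out, "converged") <- TRUE
    attr(out, "rmse") <- 0
    return(out)
  }

  offset0 <- mean(utils::tail(y, 3L))
  dh0 <- y[1L] - offset0
  if (abs(dh0) < 1e-9) dh0 <- -1
  # theta: (n), log10 kd, dh, offset
  make_theta <- function(n, kd, dh, off) {
    th <- c(log10_kd = log10(kd), delta_h = dh, offset = off)
    if (is.null(fix_n)) th <- c(n = n, th)
    th
  }
  split_theta <- function(th) {
    n <- if (is.null(fix_n)) th[["n"]] else fix_n
    list(n = n, kd = 10^th[["log10_kd"]], dh = th[["delta_h"]],
         off = th[["offset"]])
  }
  resid_fn <- function(th) {
    p <- split_theta(th)
    if (p$n <= 0) return(rep(1e6, length(y)))
    predict_heats(p$n, p$kd, p$dh, p$off) - y
  }
  obj <- function(th) {
    r <- tryCatch(resid_fn(th), error = function(e) rep(1e6, length(y)))
    sum(w * r^2)
  }
  starts <- list(make_theta(1, 1e-6, dh0, offset0),
                 make_theta(1, 1e-7, dh0, offset0),
                 make_theta(0.8, 1e-5, dh0, offset0))
  best <- NULL
  for (s in starts) {
    o <- stats::nlminb(s, obj, control = list(iter.max = 500L, eval.max = 2000L))
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  p <- split_theta(best$par)
  n_par <- length(best$par)
  dof <- max(length(y) - n_par, 1L)
  rmse <- sqrt(best$objective / dof)
  J <- num_jacobian(resid_fn, best$par, h = 1e-6)
  sds <- stats::setNames(param_sd(J, w, rmse^2), names(best$par))

  out <- binding_params(p$n, p$kd, p$dh, p$off, protocol$temperature)
  cc <- itc_displaced_concentrations(protocol)
  cval <- p$n * cc$m_t[1L] / p$kd
  attr(out, "sd") <- sds
  attr(out, "c_value") <- cval
  attr(out, "low_information") <- cval < 1 || cval > 1000
  attr(out, "converged") <- best$convergence == 0L
  attr(out, "rmse") <- rmse
  attr(out, "kd_undetermined") <- FALSE
  if (!attr(out, "converged")) {
    warning(sprintf("one-site fit did not converge (nlminb message: %s)",
                    best$message), call. = FALSE)
  }
  out
}

#' Average binding parameters over replicate fits
#'
#' Arithmetic means of n, Kd and dH (how "mean of replicates" figures are
#' reported); derived terms recomputed from the mean Kd.
#'
#' @param fits List of [binding_params()] at a common temperature.
#' @return A `binding_params`.
#' @export
average_binding_params <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "binding_params")))
  tt <- vapply(fits, `[[`, 0, "temperature")
  if (max(tt) - min(tt) > 1e-9) {
    stop("replicates must share a temperature", call. = FALSE)
  }
  binding_params(mean(vapply(fits, `[[`, 0, "n")),
                 mean(vapply(fits, `[[`, 0, "k_d")),
                 mean(vapply(fits, `[[`, 0, "delta_h")),
                 mean(vapply(fits, `[[`, 0, "dilution_offset")),
                 tt[1L])
}
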