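#' Generate a synthetic 31P titration dataset
#'
#' Forward-models fast-exchange shifts over a pH grid with [predict_shifts()]
#' and adds i.i.d. Gaussian noise in ppm; optionally masks a random subset of
#' observations to mimic exchange-broadened, undetectable peaks.  All
#' randomness is Mersenne-Twister under `seed`, so identical arguments give
#' identical datasets.
#'
#' @param model A [chem_model()].
#' @param basis A [shift_basis()] covering every populated species (default:
#'   the synthetic [demo_shift_basis()]).
#' @param ph_grid pH values (default 3.0-12.5 in 0.5 steps, the packaged
#'   titration design).
#' @param conditions [solution_conditions()] template (default 1 mM ligand,
#'   no metals).
#' @param noise_sd_ppm Gaussian noise sd (default 0.02 ppm).
#' @param missing_rate Probability that an individual observation is masked
#'   (points keep at least one nucleus).
#' @param seed Integer seed.
#' @return A [titration_dataset()].
#' @export
gen_titration <- function(model, basis = demo_shift_basis(model),
                          ph_grid = seq(3, 12.5, by = 0.5),
                          conditions = solution_conditions(1e-3),
                          noise_sd_ppm = 0.02, missing_rate = 0,
                          seed = NULL) {
  clean <- vapply(ph_grid, function(p) {
    predict_shifts(model, basis,
                   solution_conditions(conditions$total_ligand,
                                       conditions$total_k,
                                       conditions$total_mg, p))
  }, numeric(ncol(basis)))
  clean <- matrix(clean, nrow = length(ph_grid), ncol = ncol(basis),
                  byrow = TRUE, dimnames = list(NULL, colnames(basis)))
  obs <- with_seed(seed, {
    noisy <- clean + if (noise_sd_ppm > 0) {
      matrix(stats::rnorm(length(clean), 0, noise_sd_ppm), nrow(clean))
    } else 0
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(noisy)) < missing_rate, nrow(noisy))
      # never blank out a whole point
      full_rows <- rowSums(!mask) == 0L
      mask[full_rows, 1L] <- FALSE
      noisy[mask] <- NA_real_
    }
    noisy
  })
  titration_dataset(ph_grid, obs, conditions)
}

#' Generate a synthetic conformer-equilibrium series
#'
#' \eqn{K(T) = \exp(-(\Delta H^0 - T\Delta S^0)/(RT))} on a temperature grid
#' with multiplicative log-normal noise (ratios of integrals are positive, so
#' noise is Gaussian on ln K), replicated as in the pooled-regression design.
#'
#' @param params A [thermo_params()] (generator truth).
#' @param t_grid Kelvin grid (default 274-283 K in 1 K steps).
#' @param ln_k_noise_sd Gaussian sd on ln K (0 = noiseless).
#' @param replicates Number of replicate series (default 2).
#' @param seed Integer seed.
#' @return A [conformer_series()] with `replicates * length(t_grid)` rows.
#' @export
gen_conformer_series <- function(params, t_grid = 274:283,
                                 ln_k_noise_sd = 0, replicates = 2L,
                                 seed = NULL) {
  if (any(t_grid < 150 | t_grid > 400)) {
    stop("t_grid outside a physically sensible range (150-400 K)",
         call. = FALSE)
  }
  k0 <- exp(-(params$delta_h - t_grid * params$delta_s) / (R_KCAL * t_grid))
  tt <- rep(t_grid, replicates)
  rep_id <- rep(seq_len(replicates), each = length(t_grid))
  k <- with_seed(seed, {
    kk <- rep(k0, replicates)
    if (ln_k_noise_sd > 0) {
      kk <- kk * exp(stats::rnorm(length(kk), 0, ln_k_noise_sd))
    }
    kk
  })
  conformer_series(tt, k, rep_id)
}

#' Generate a synthetic ITC isotherm
#'
#' Delegates to [simulate_isotherm()] with seeded Gaussian heat noise.
#'
#' @param protocol An [itc_protocol()].
#' @param params A [binding_params()].
#' @param noise_sd Heat noise sd, kcal/mol.
#' @param seed Integer seed.
#' @return An `isotherm`.
#' @export
gen_itc <- function(protocol, params, noise_sd = 0, seed = NULL) {
  simulate_isotherm(protocol, params, noise_sd = noise_sd, seed = seed)
}
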