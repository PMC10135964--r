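# Internal helpers shared across modules.

# Gas constant, kcal/(mol K); used by the van't Hoff and ITC code paths.
R_KCAL <- 1.987204e-3

# Evaluate `code` under a fixed seed (Mersenne-Twister), restoring the
# caller's RNG state afterwards so seeded generators never perturb a
# surrounding simulation.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(fn, x, h = 1e-5) {
  f0 <- fn(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (k in seq_along(x)) {
    hk <- h * max(1, abs(x[k]))
    xp <- x; xp[k] <- x[k] + hk
    xm <- x; xm[k] <- x[k] - hk
    J[, k] <- (fn(xp) - fn(xm)) / (2 * hk)
  }
  J
}

# Parameter standard deviations from a residual Jacobian (Gauss-Newton
# curvature): cov = sigma^2 (J'WJ)^-1.
param_sd <- function(J, w, sigma2) {
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(solve(JtWJ) * sigma2, error = function(e) NULL)
  if (is.null(cov)) return(rep(NA_real_, ncol(J)))
  v <- diag(cov)
  ifelse(v >= 0, sqrt(v), NA_real_)
}
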