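# Independent oracles, deliberately brute-force and separate from the
# package's code paths.

# Mass-balance speciation by nested bisection for models with at most two
# free unknowns (L, or L + K).  Residuals are monotone in the own log10 free
# concentration, so plain bisection is exact.
oracle_speciation <- function(model, cond, tol = 1e-12) {
  tab <- model$tab
  stopifnot(all(tab$n_mg == 0), cond$total_mg == 0)
  alpha <- tab$log_beta - tab$n_h * cond$ph
  calc <- function(x_l, x_k) {
    c_j <- 10^(alpha + tab$n_l * x_l + tab$n_k * x_k)
    list(l = sum(tab$n_l * c_j), k = sum(tab$n_k * c_j) + 10^x_k, c_j = c_j)
  }
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  solve_l <- function(x_k) {
    bisect(function(x) calc(x, x_k)$l - cond$total_ligand,
           -40, log10(cond$total_ligand) + 1)
  }
  if (cond$total_k == 0) {
    x_k <- -Inf
    x_l <- solve_l(-Inf)
  } else {
    x_k <- bisect(function(xk) calc(solve_l(xk), xk)$k - cond$total_k,
                  -40, log10(cond$total_k) + 1)
    x_l <- solve_l(x_k)
  }
  cc <- calc(x_l, x_k)
  list(free_l = 10^x_l, free_k = if (is.finite(x_k)) 10^x_k else 0,
       concentrations = stats::setNames(cc$c_j, tab$id),
       ligand_fractions = stats::setNames(cc$c_j * tab$n_l /
                                            cond$total_ligand, tab$id))
}

# 1-D brute-force scan of the titration objective for a monoprotic model:
# for each trial log beta, solve speciation analytically and project the two
# limiting shifts by ordinary least squares.
oracle_monoprotic_scan <- function(data, grid) {
  ssq <- vapply(grid, function(lb) {
    f_hl <- 10^(lb - data$ph) / (1 + 10^(lb - data$ph))
    X <- cbind(L = 1 - f_hl, HL = f_hl)
    y <- data$observed[, 1L]
    r <- stats::lm.fit(X, y)$residuals
    sum(r^2)
  }, 0)
  grid[which.min(ssq)]
}

# Per-injection heats from the one-site binding quadratic solved numerically
# (uniroot on the complex concentration), independent of the closed form.
oracle_itc_heats <- function(protocol, params) {
  v0 <- protocol$cell_volume_ul
  v0_l <- v0 * 1e-6
  dvc <- protocol$cumulative_volume_ul
  m_t <- protocol$cell_conc * (1 - dvc / (2 * v0)) / (1 + dvc / (2 * v0))
  x_t <- protocol$syringe_conc * (dvc / v0) / (1 + dvc / (2 * v0))
  q <- numeric(length(dvc))
  for (i in seq_along(dvc)) {
    sites <- params$n * m_t[i]
    f <- function(mx) params$k_d - (sites - mx) * (x_t[i] - mx) / mx
    mx <- stats::uniroot(f, c(1e-18, min(sites, x_t[i]) * (1 - 1e-12)),
                         tol = 1e-16)$root
    q[i] <- mx * params$delta_h * v0_l
  }
  q_prev <- c(0, q[-length(q)])
  dv <- protocol$injection_volumes_ul
  dq <- q + (dv / v0) * (q + q_prev) / 2 - q_prev
  dq / (protocol$syringe_conc * dv * 1e-6) + params$dilution_offset
}
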