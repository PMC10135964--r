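#' Solution conditions for one speciation point
#'
#' Totals are analytical (weighed-in) concentrations; protons are buffered at
#' the metered pH, so `[H+] = 10^-ph` is an input, not a mass-balanced
#' unknown (no hydroxo species occur in the packaged models, so pKw never
#' enters).
#'
#' @param total_ligand,total_k,total_mg Total concentrations, mol/L (>= 0).
#' @param ph -log10 of the free hydrogen-ion concentration, in `[0, 14]`.
#' @return A `solution_conditions` list.
#' @export
solution_conditions <- function(total_ligand, total_k = 0, total_mg = 0,
                                ph = 7) {
  if (any(c(total_ligand, total_k, total_mg) < 0)) {
    stop("totals must be non-negative", call. = FALSE)
  }
  if (ph < 0 || ph > 14) stop("ph must lie in [0, 14]", call. = FALSE)
  structure(list(total_ligand = total_ligand, total_k = total_k,
                 total_mg = total_mg, ph = ph),
            class = "solution_conditions")
}

#' Solver controls for [solve_point()]
#'
#' @param tol Convergence threshold on the maximum relative mass-balance
#'   residual.
#' @param max_iter Maximum Newton iterations.
#' @param max_halvings Maximum step halvings per damped Newton step.
#' @param max_step Cap on a Newton step in log10 concentration units.
#' @export
speciation_control <- function(tol = 1e-10, max_iter = 200L,
                               max_halvings = 20L, max_step = 2) {
  list(tol = tol, max_iter = max_iter, max_halvings = max_halvings,
       max_step = max_step)
}

#' Solve the mass-balance equations at one condition
#'
#' Free concentrations of L, K+ and Mg2+ are found by damped Newton iteration
#' on log10 scale (positivity is automatic); every species concentration then
#' follows from the mass-action law
#' \eqn{c_j = \beta_j [H]^{h_j} [K]^{k_j} [Mg]^{m_j} [L]^{l_j}}.
#' Components with zero total are excluded (free concentration 0; species
#' requiring them are absent).  Initialization scales 10% of each total and
#' pre-balances with a few fixed-point sweeps; [speciation_diagram()] warm
#' starts from the neighbouring pH instead.
#'
#' @param model A [chem_model()].
#' @param cond A [solution_conditions()].
#' @param start Optional named log10 free-concentration vector
#'   (`c(L=, K=, Mg=)`) used as warm start.
#' @param control See [speciation_control()].
#' @return A `speciation_result`: `free` (named mol/L), `concentrations`
#'   (named by species id), `ligand_fractions` (mole fraction of total
#'   ligand), `converged`, `residual` (max relative mass-balance error),
#'   `iterations`, `ph`.
#' @examples
#' toy <- chem_model("HA", -1, list(
#'   species_def("L"), species_def("HL", n_h = 1, log_beta = 7)))
#' r <- solve_point(toy, solution_conditions(1e-3, ph = 7))
#' r$ligand_fractions  # 0.5 / 0.5 at the pKa midpoint
#' @export
solve_point <- function(model, cond, start = NULL,
                        control = speciation_control()) {
  stopifnot(inherits(model, "chem_model"))
  if (!inherits(cond, "solution_conditions")) {
    cond <- do.call(solution_conditions, cond)
  }
  tab <- model$tab
  totals <- c(L = cond$total_ligand, K = cond$total_k, Mg = cond$total_mg)
  if (all(totals == 0)) stop("at least one total must be positive", call. = FALSE)
  stoich <- cbind(L = tab$n_l, K = tab$n_k, Mg = tab$n_mg)
  rownames(stoich) <- tab$id
  # conditional constants at fixed [H+]
  alpha <- tab$log_beta - tab$n_h * cond$ph
  active <- names(totals)[totals > 0]
  feasible <- rowSums(stoich[, setdiff(names(totals), active), drop = FALSE]) == 0
  S <- stoich[feasible, active, drop = FALSE]
  a <- alpha[feasible]
  has_free_ion <- stats::setNames(active %in% c("K", "Mg"), active)
  tot <- totals[active]
  ln10 <- log(10)

  logc_of <- function(x) pmin(a + drop(S %*% x), 300)
  calc_tot <- function(x, c_j) {
    drop(crossprod(S, c_j)) + ifelse(has_free_ion, 10^x, 0)
  }
  resid_of <- function(x) {
    c_j <- 10^logc_of(x)
    (calc_tot(x, c_j) - tot) / tot
  }

  if (!is.null(start)) {
    x <- start[active]
    if (any(!is.finite(x))) start <- NULL
  }
  if (is.null(start)) {
    x <- stats::setNames(log10(0.1 * tot), active)
    # fixed-point pre-balance: each sweep rescales one component's free
    # concentration by the current overshoot (exact when that component
    # enters every dominating species first-order)
    for (sweep in 1:12) {
      for (cc in active) {
        c_j <- 10^logc_of(x)
        calc <- calc_tot(x, c_j)[cc]
        if (calc > 0) {
          adj <- log10(calc / tot[cc])
          ord <- max(1, max(S[c_j > 0.5 * calc / nrow(S), cc], 1))
          x[cc] <- x[cc] - min(max(adj / ord, -6), 6)
        }
      }
    }
  }

  f <- resid_of(x)
  iter <- 0L
  converged <- max(abs(f)) < control$tol
  while (!converged && iter < control$max_iter) {
    iter <- iter + 1L
    c_j <- 10^logc_of(x)
    # Jacobian of scaled residuals wrt log10 free concentrations
    J <- ln10 * (crossprod(S * c_j, S) + diag(ifelse(has_free_ion, 10^x, 0),
                                              nrow = length(x))) / tot
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      step <- -f / diag(J)  # fall back to a diagonal (scaled gradient) step
    }
    big <- max(abs(step))
    if (big > control$max_step) step <- step * control$max_step / big
    lambda <- 1
    f0 <- max(abs(f))
    for (h in 0:control$max_halvings) {
      xn <- x + lambda * step
      fn <- resid_of(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < f0) break
      lambda <- lambda / 2
    }
    x <- xn; f <- fn
    converged <- max(abs(f)) < control$tol
  }

  conc <- stats::setNames(numeric(nrow(tab)), tab$id)
  conc[rownames(S)] <- 10^logc_of(x)
  free <- c(L = 0, K = 0, Mg = 0)
  free[active] <- 10^x
  if ("L" %in% active) free["L"] <- conc[tab$id[tab$n_h == 0L & tab$n_k == 0L &
                                                  tab$n_mg == 0L]]
  frac <- if (cond$total_ligand > 0) {
    tab$n_l * conc / cond$total_ligand
  } else rep(NA_real_, nrow(tab))
  names(frac) <- tab$id
  structure(
    list(free = free, concentrations = conc, ligand_fractions = frac,
         converged = converged, residual = max(abs(f)), iterations = iter,
         ph = cond$ph, log_free = stats::setNames(x, active)),
    class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("<speciation_result> pH %.2f, %s (residual %.2e, %d iter)\n",
              x$ph, if (x$converged) "converged" else "NOT CONVERGED",
              x$residual, x$iterations))
  top <- sort(x$ligand_fractions, decreasing = TRUE)
  print(round(utils::head(top, 6), 4))
  invisible(x)
}

#' Species distribution diagram over a pH grid
#'
#' Solves [solve_point()] at each grid pH with continuation (warm start from
#' the previous point) and tabulates ligand mole fractions — the computation
#' behind HySS-style speciation diagrams.
#'
#' @param model A [chem_model()].
#' @param cond_template A [solution_conditions()] whose `ph` is ignored.
#' @param ph_grid Monotone numeric vector of pH values.
#' @param control See [speciation_control()].
#' @return A data.frame of class `speciation_diagram` with columns `ph`,
#'   `free_L`, `free_K`, `free_Mg` and one fraction column per species id.
#' @export
speciation_diagram <- function(model, cond_template, ph_grid,
                               control = speciation_control()) {
  stopifnot(length(ph_grid) >= 1L)
  if (is.unsorted(ph_grid) && is.unsorted(rev(ph_grid))) {
    stop("ph_grid must be monotone", call. = FALSE)
  }
  ids <- model$tab$id
  out <- vector("list", length(ph_grid))
  warm <- NULL
  for (i in seq_along(ph_grid)) {
    cond <- solution_conditions(cond_template$total_ligand,
                                cond_template$total_k,
                                cond_template$total_mg, ph_grid[i])
    r <- solve_point(model, cond, start = warm, control = control)
    if (!r$converged) {
      # retry cold before giving up
      r <- solve_point(model, cond, start = NULL, control = control)
      if (!r$converged) {
        stop(sprintf("speciation failed to converge at pH %.3f (residual %.3e)",
                     ph_grid[i], r$residual), call. = FALSE)
      }
    }
    warm <- r$log_free
    out[[i]] <- c(ph = ph_grid[i], free_L = r$free[["L"]],
                  free_K = r$free[["K"]], free_Mg = r$free[["Mg"]],
                  r$ligand_fractions)
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("ph", "free_L", "free_K", "free_Mg", ids)
  class(df) <- c("speciation_diagram", "data.frame")
  attr(df, "species_ids") <- ids
  df
}

#' Most abundant ligand species
#'
#' For a single [solve_point()] result, the argmax of the ligand fractions;
#' for a [speciation_diagram()], the argmax of the mean fraction over the
#' grid (the reading used for "most abundant in the pH range" statements).
#' Exact ties break lexicographically by id and are flagged in the
#' `"tie"` attribute.
#'
#' @param x A `speciation_result` or `speciation_diagram`.
#' @return Species id (character scalar) with attributes `fraction` and
#'   `tie`.
#' @export
most_abundant_species <- function(x) UseMethod("most_abundant_species")

#' @export
most_abundant_species.speciation_result <- function(x) {
  if (!isTRUE(x$converged)) {
    stop("refusing to rank species of a non-converged result", call. = FALSE)
  }
  pick_argmax(x$ligand_fractions)
}

#' @export
most_abundant_species.speciation_diagram <- function(x) {
  ids <- attr(x, "species_ids")
  pick_argmax(colMeans(as.data.frame(x)[, ids, drop = FALSE]))
}

pick_argmax <- function(frac) {
  frac <- frac[order(names(frac))]  # lexicographic tie-break
  top <- max(frac)
  winner <- names(frac)[which(frac == top)[1L]]
  structure(winner, fraction = unname(top),
            tie = sum(frac == top) > 1L)
}

#' Mean protonation number of the ligand
#'
#' \eqn{\bar n_H = \sum_j h_j f_j} over ligand species — non-increasing in pH
#' for any H+-only model.
#'
#' @param model A [chem_model()].
#' @param result A `speciation_result` from that model.
#' @return Numeric scalar.
#' @export
mean_protonation <- function(model, result) {
  sum(model$tab$n_h * result$ligand_fractions)
}
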