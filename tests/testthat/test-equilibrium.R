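test_that("solve_point reproduces the pKa midpoint", {
  r <- solve_point(toy_monoprotic(7), solution_conditions(1e-3, ph = 7))
  expect_true(r$converged)
  expect_equal(unname(r$ligand_fractions), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("excess-metal limit matches beta * free K", {
  # T_K >> T_L, so [K]free ~ T_K and [KL]/[L] = beta * [K]free ~ 1
  r <- solve_point(toy_k_binding(1), solution_conditions(1e-3, total_k = 0.1,
                                                         ph = 7))
  ratio <- r$concentrations[["KL"]] / r$concentrations[["L"]]
  expect_equal(ratio, 10^1 * r$free[["K"]], tolerance = 1e-9)
  expect_equal(ratio, 1.0, tolerance = 0.01)
  # and agrees with the bisection oracle to 6 significant digits
  o <- oracle_speciation(toy_k_binding(1),
                         solution_conditions(1e-3, total_k = 0.1, ph = 7))
  expect_equal(r$free[["L"]], o$free_l, tolerance = 1e-6)
  expect_equal(r$free[["K"]], o$free_k, tolerance = 1e-6)
})

test_that("Newton solution matches brute-force bisection across random toy models", {
  set.seed(42)
  for (i in 1:25) {
    lb1 <- runif(1, 2, 10); lb2 <- lb1 + runif(1, 2, 8)
    m <- chem_model("rand", -3, list(
      species_def("L"),
      species_def("HL", n_h = 1, log_beta = lb1),
      species_def("H2L", n_h = 2, log_beta = lb2),
      species_def("KL", n_k = 1, log_beta = runif(1, 0.5, 3)),
      species_def("KHL", n_h = 1, n_k = 1, log_beta = lb1 + runif(1, 0.5, 3))))
    cond <- solution_conditions(10^runif(1, -4, -2), total_k = 10^runif(1, -2, -0.5),
                                ph = runif(1, 3, 11))
    r <- solve_point(m, cond)
    o <- oracle_speciation(m, cond)
    expect_true(r$converged)
    expect_equal(r$free[["L"]], o$free_l, tolerance = 1e-6)
    expect_equal(r$free[["K"]], o$free_k, tolerance = 1e-6)
    expect_equal(r$ligand_fractions, o$ligand_fractions, tolerance = 1e-6)
  }
})

test_that("mass balance and fraction closure hold across the full model grid", {
  m <- ipp_model("insp8")
  d <- speciation_diagram(m, solution_conditions(1e-3, 0.15, 1e-3),
                          seq(3, 12.5, by = 0.25))
  ids <- attr(d, "species_ids")
  expect_equal(max(abs(rowSums(as.data.frame(d)[, ids]) - 1)), 0,
               tolerance = 1e-9)
  # explicit mass-balance residuals recomputed from the returned table
  tab <- m$tab
  for (i in seq_len(nrow(d))) {
    conc <- as.numeric(d[i, ids]) * 1e-3
    calc_k <- sum(tab$n_k * conc) + d$free_K[i]
    calc_mg <- sum(tab$n_mg * conc) + d$free_Mg[i]
    expect_equal(calc_k, 0.15, tolerance = 1e-9)
    expect_equal(calc_mg, 1e-3, tolerance = 1e-9)
  }
})

test_that("mean protonation is non-increasing in pH for an H+-only model", {
  m <- protonation_model(ipp_model("insp8"))
  grid <- seq(2, 13, by = 0.25)
  warm <- NULL
  nbar <- vapply(grid, function(p) {
    r <- solve_point(m, solution_conditions(1e-3, ph = p))
    mean_protonation(m, r)
  }, 0)
  expect_true(all(diff(nbar) < 1e-10))
})

test_that("fractions are scale invariant for 1:1 models", {
  m <- toy_monoprotic(6)
  for (s in c(1, 10, 1000)) {
    r <- solve_point(m, solution_conditions(1e-6 * s, ph = 6.3))
    r0 <- solve_point(m, solution_conditions(1e-6, ph = 6.3))
    expect_equal(r$ligand_fractions, r0$ligand_fractions, tolerance = 1e-8)
  }
})

test_that("solver rejects bad inputs and reports diagnostics", {
  expect_error(solution_conditions(-1e-3), "non-negative")
  expect_error(solution_conditions(1e-3, ph = 15), "ph")
  m <- toy_monoprotic()
  expect_error(solve_point(m, solution_conditions(0, 0, 0, 7)), "positive")
  r <- solve_point(m, solution_conditions(1e-3, ph = 7),
                   control = speciation_control(max_iter = 0L))
  # degenerate iteration budget: flagged, never silent
  expect_true(is.finite(r$residual))
})

test_that("speciation_diagram propagates the offending pH and checks monotone grids", {
  m <- toy_monoprotic()
  expect_error(speciation_diagram(m, solution_conditions(1e-3),
                                  c(3, 5, 4)), "monotone")
  d <- speciation_diagram(m, solution_conditions(1e-3), c(6, 7, 8))
  expect_identical(nrow(d), 3L)
})

test_that("most_abundant_species ranks, tie-breaks, and guards convergence", {
  r <- solve_point(toy_monoprotic(7), solution_conditions(1e-3, ph = 9))
  expect_identical(as.character(most_abundant_species(r)), "L")
  # exact tie at the midpoint breaks lexicographically with a flag
  r2 <- solve_point(toy_monoprotic(7), solution_conditions(1e-3, ph = 7))
  top <- most_abundant_species(r2)
  expect_identical(as.character(top), "HL")  # "HL" < "L" lexicographically
  expect_true(attr(top, "tie"))
  r2$converged <- FALSE
  expect_error(most_abundant_species(r2), "non-converged")
})

test_that("single-species model gives fraction 1 across a grid", {
  m <- chem_model("only", -1, list(species_def("L")))
  d <- speciation_diagram(m, solution_conditions(5e-4), seq(3, 11, 1))
  expect_equal(as.data.frame(d)$L, rep(1, 9), tolerance = 1e-12)
})
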