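test_that("predicted shifts are population-weighted and convex", {
  m <- toy_monoprotic(7)
  b <- mono_basis(2, 0)
  # single species populated -> its limiting shift
  expect_equal(unname(predict_shifts(m, b, solution_conditions(1e-3, ph = 12))),
               2, tolerance = 1e-4)
  # 50/50 -> arithmetic mean
  expect_equal(unname(predict_shifts(m, b, solution_conditions(1e-3, ph = 7))),
               1, tolerance = 1e-9)
  # upfield with decreasing pH, always inside the basis hull
  sweep <- vapply(seq(4, 10, 0.5), function(p) {
    unname(predict_shifts(m, b, solution_conditions(1e-3, ph = p)))
  }, 0)
  expect_true(all(diff(sweep) > 0))  # increasing with pH = upfield as pH drops
  expect_true(all(sweep >= 0 & sweep <= 2))
})

test_that("predict_shifts demands basis coverage of populated species", {
  m <- toy_monoprotic(7)
  b <- shift_basis(matrix(2, 1, 1, dimnames = list("L", "P1")))
  expect_error(predict_shifts(m, b, solution_conditions(1e-3, ph = 7)),
               "lacks populated species")
})

test_that("noiseless monoprotic fit recovers the constant against a brute-force scan", {
  m <- toy_monoprotic(7)
  d <- gen_titration(m, mono_basis(), ph_grid = seq(4, 10, 0.5),
                     noise_sd_ppm = 0)
  f <- fit_titration(d, m, start = c(HL = 6.2))
  expect_true(f$converged)
  expect_equal(f$refined$log_beta, 7, tolerance = 1e-3)
  expect_lt(f$refined$sd, 0.01)
  expect_lt(f$sigma, 1e-6)
  # refined shifts equal the generator basis
  expect_equal(f$basis["L", "P1"], 2, tolerance = 1e-4)
  expect_equal(f$basis["HL", "P1"], 0, tolerance = 1e-4)
  # independent 1-D scan lands on the same optimum
  scan <- oracle_monoprotic_scan(d, seq(6.5, 7.5, by = 0.001))
  expect_equal(f$refined$log_beta, scan, tolerance = 2e-3)
})

test_that("missing observations reduce n_obs and do not break the fit", {
  m <- toy_diprotic()
  d <- gen_titration(m, di_basis(), ph_grid = seq(2.5, 9.5, 0.5),
                     noise_sd_ppm = 0)
  obs <- d$observed
  obs[c(3, 7), "P2"] <- NA
  d2 <- titration_dataset(d$ph, obs, d$conditions)
  f <- fit_titration(d2, m)
  f_full <- fit_titration(d, m)
  expect_identical(f$n_obs, f_full$n_obs - 2L)
  expect_equal(f$refined$log_beta, c(9, 14), tolerance = 1e-3)
})

test_that("never-populated species are flagged undetermined, not fitted", {
  m <- chem_model("HA", -1, list(
    species_def("L"),
    species_def("HL", n_h = 1, log_beta = 7),
    species_def("H2L", n_h = 2, log_beta = 8)))  # pKa2 ~ 1, far below grid
  d <- gen_titration(m, shift_basis(matrix(c(2, 0, -1), 3, 1,
                                           dimnames = list(c("L", "HL", "H2L"), "P1"))),
                     ph_grid = seq(5.5, 9.5, 0.5), noise_sd_ppm = 0)
  f <- fit_titration(d, m, refine = "HL")
  expect_true("H2L" %in% f$undetermined)
  expect_true(is.na(f$basis["H2L", "P1"]))
})

test_that("well-separated constants are recovered within 3 sd under noise", {
  m <- toy_diprotic(9, 14)   # stepwise 9 and 5: well identified
  truth <- c(HL = 9, H2L = 14)
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    d <- gen_titration(m, di_basis(), ph_grid = seq(2.5, 11.5, 0.5),
                       noise_sd_ppm = 0.02, seed = 1000 + s)
    f <- fit_titration(d, m, start = truth + 0.4)
    err <- abs(f$refined$log_beta - truth)
    if (all(err <= 3 * pmax(f$refined$sd, 1e-6))) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})

test_that("model selection prefers parsimony on ties and fit quality otherwise", {
  true_m <- toy_monoprotic(7)
  spurious <- chem_model("HA+ghost", -1, list(
    species_def("L"),
    species_def("HL", n_h = 1, log_beta = 7),
    species_def("H2L", n_h = 2, log_beta = 9.5)))
  d <- gen_titration(true_m, mono_basis(), ph_grid = seq(4, 10, 0.5),
                     noise_sd_ppm = 0)
  rk <- model_selection(d, list(spurious, true_m))
  expect_identical(rk$table$ligand[1L], "HA")     # fewer species wins the tie
  # diprotic data: diprotic model wins on sigma outright
  d2 <- gen_titration(toy_diprotic(), di_basis(), ph_grid = seq(2.5, 9.5, 0.5),
                      noise_sd_ppm = 0.01, seed = 7)
  mono_cand <- chem_model("mono", -2, list(
    species_def("L"), species_def("HL", n_h = 1, log_beta = 9)))
  rk2 <- model_selection(d2, list(mono_cand, toy_diprotic()))
  expect_identical(rk2$table$ligand[1L], "H2A")
  expect_lt(rk2$table$sigma[1L], rk2$table$sigma[2L])
  # single candidate comes back with statistics
  rk3 <- model_selection(d, list(true_m))
  expect_identical(nrow(rk3$table), 1L)
  expect_true(is.finite(rk3$table$chi_square))
})

test_that("model selection reports total failure explicitly", {
  d <- gen_titration(toy_monoprotic(7), mono_basis(),
                     ph_grid = seq(6, 8, 0.5), noise_sd_ppm = 0)
  # one refined constant + 2 basis shifts = 3 params vs 5 obs is fine, but an
  # overparameterized candidate (4 species x 1 nucleus + 3 constants > obs) fails
  over <- chem_model("over", -3, list(
    species_def("L"), species_def("HL", n_h = 1, log_beta = 7),
    species_def("H2L", n_h = 2, log_beta = 13.5),
    species_def("H3L", n_h = 3, log_beta = 19.5)))
  expect_error(model_selection(d, list(over)), "all candidate models failed")
})

test_that("protonation step shifts identify sites and degenerate cases", {
  m <- toy_diprotic(9, 14)
  b <- shift_basis(matrix(c(2, 2, 2, 1, 2, 2, 1, 1, 2), 3, 3, byrow = TRUE,
                          dimnames = list(c("L", "HL", "H2L"),
                                          c("P1", "P2", "P3"))))
  st <- protonation_step_shifts(m, b)
  expect_length(st, 2L)
  expect_identical(st[[1]]$inferred_sites, "P1")   # only P1 moves on step 1
  expect_identical(st[[2]]$inferred_sites, "P2")
  # all-zero step -> empty inference with degenerate flag
  b0 <- shift_basis(matrix(2, 3, 3, dimnames = dimnames(b)))
  st0 <- protonation_step_shifts(m, b0)
  expect_identical(st0[[1]]$inferred_sites, character(0))
  expect_true(st0[[1]]$degenerate)
  # gap in the ladder is an error
  gap <- chem_model("gap", -3, list(
    species_def("L"), species_def("H2L", n_h = 2, log_beta = 14)))
  expect_error(protonation_step_shifts(gap, b), "consecutive")
})

test_that("demo basis mimics the reported step-1 protonation sites", {
  m <- protonation_model(ipp_model("insp8"))
  st <- protonation_step_shifts(m, demo_shift_basis(m), margin = 1.0)
  expect_setequal(st[[1]]$inferred_sites, c("P3", "P5b", "P1b"))
  # protonation never shifts any nucleus downfield in the synthetic basis
  expect_true(all(vapply(st, function(s) max(s$delta_delta) <= 0, TRUE)))
})

test_that("titration_dataset validates its contract", {
  expect_error(titration_dataset(c(3, 3), matrix(1, 2, 1,
                                                 dimnames = list(NULL, "P1")),
                                 solution_conditions(1e-3)), "distinct")
  expect_error(titration_dataset(c(3, 4), matrix(c(1, NA), 2, 1,
                                                 dimnames = list(NULL, "P1")),
                                 solution_conditions(1e-3)),
               "at least one observed")
})
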