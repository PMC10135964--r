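# Small models built in code, shared across test files.

toy_monoprotic <- function(log_beta = 7) {
  chem_model("HA", -1, list(
    species_def("L"),
    species_def("HL", n_h = 1, log_beta = log_beta)))
}

toy_diprotic <- function(lb1 = 9, lb2 = 14) {
  chem_model("H2A", -2, list(
    species_def("L"),
    species_def("HL", n_h = 1, log_beta = lb1),
    species_def("H2L", n_h = 2, log_beta = lb2)))
}

toy_k_binding <- function(log_beta = 1) {
  chem_model("KA", -1, list(
    species_def("L"),
    species_def("KL", n_k = 1, log_beta = log_beta)))
}

mono_basis <- function(d_l = 2, d_hl = 0) {
  shift_basis(matrix(c(d_l, d_hl), 2, 1, dimnames = list(c("L", "HL"), "P1")))
}

di_basis <- function() {
  shift_basis(matrix(c(2.0, 0.9, -0.5, 1.0, 1.0, -1.2), 3, 2,
                     dimnames = list(c("L", "HL", "H2L"), c("P1", "P2"))))
}
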