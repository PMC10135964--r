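# InsP6 (phytate) equilibrium model, I = 0.15 M, T = 37 C, potentiometry.
# log_beta are cumulative constants (see insp8.model for the convention).
ligand: InsP6
base_charge: -12
medium: I = 0.15 M; T = 37 C; potentiometry
species:
id       display          n_h n_k n_mg n_l log_beta conformer    charge
L        L12-             0   0   0    1   0        unspecified  -12
HL       (HL)11-          1   0   0    1   10.8     unspecified  -11
H2L      (H2L)10-         2   0   0    1   21.3     unspecified  -10
H3L      (H3L)9-          3   0   0    1   31.63    unspecified  -9
H4L      (H4L)8-          4   0   0    1   40.42    unspecified  -8
H5L      (H5L)7-          5   0   0    1   47.32    unspecified  -7
H6L      (H6L)6-          6   0   0    1   53.04    unspecified  -6
H7L      (H7L)5-          7   0   0    1   56.14    unspecified  -5
K4H3L    [K4(H3L)]5-      3   4   0    1   37.05    unspecified  -5
K3H4L    [K3(H4L)]5-      4   3   0    1   43.78    unspecified  -5
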