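# 5PCP-InsP5 (non-hydrolyzable methylene-bisphosphonate analogue of
# 5PP-InsP5) equilibrium model, I = 0.15 M, T = 22 C, 31P NMR.
# log_beta are cumulative constants (see insp8.model for the convention).
ligand: 5PCP-InsP5
base_charge: -13
medium: I = 0.15 M; T = 22 C; 31P NMR
species:
id       display          n_h n_k n_mg n_l log_beta conformer    charge
L        L13-             0   0   0    1   0        unspecified  -13
HL       (HL)12-          1   0   0    1   11.48    unspecified  -12
H2L      (H2L)11-         2   0   0    1   22.42    unspecified  -11
H3L      (H3L)10-         3   0   0    1   32.26    unspecified  -10
H4L      (H4L)9-          4   0   0    1   40.94    unspecified  -9
H5L      (H5L)8-          5   0   0    1   47.67    unspecified  -8
H6L      (H6L)7-          6   0   0    1   51.93    unspecified  -7
H7L      (H7L)6-          7   0   0    1   55.64    unspecified  -6
K5HL     [K5(HL)]7-       1   5   0    1   18.05    unspecified  -7
K4H2L    [K4(H2L)]7-      2   4   0    1   27.03    unspecified  -7
K4H3L    [K4(H3L)]6-      3   4   0    1   36.76    unspecified  -6
K3H4L    [K3(H4L)]6-      4   3   0    1   44.88    unspecified  -6
K2H5L    [K2(H5L)]6-      5   2   0    1   50.46    unspecified  -6
MgK4HL   [MgK4(HL)]6-     1   4   1    1   23.12    unspecified  -6
MgK3H2L  [MgK3(H2L)]6-    2   3   1    1   32.17    unspecified  -6
MgK3H3L  [MgK3(H3L)]5-    3   3   1    1   41.05    unspecified  -5
MgK2H4L  [MgK2(H4L)]5-    4   2   1    1   47.90    unspecified  -5
MgKH5L   [MgK(H5L)]5-     5   1   1    1   52.93    unspecified  -5
MgH6L    [Mg(H6L)]5-      6   0   1    1   56.64    unspecified  -5
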