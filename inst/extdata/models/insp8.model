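# InsP8 (1,5(PP)2-InsP4) equilibrium model, I = 0.15 M, T = 22 C, 31P NMR.
# log_beta are cumulative formation constants referenced to L^14- + free ions,
# i.e. sums of the published stepwise constants:
#   HnL:        log beta(HnL)
#   [Kk(HnL)]:  log K(k K+ + HnL) + log beta(HnL)
#   [MgKk(HnL)]: log K(Mg + k K+ + HnL) + log beta(HnL)
# Conformer labels are annotations (axial above, equatorial below the
# ring-flip transition of each series), not fitted quantities.
ligand: InsP8
base_charge: -14
medium: I = 0.15 M; T = 22 C; 31P NMR
species:
id       display          n_h n_k n_mg n_l log_beta conformer   charge
L        L14-             0   0   0    1   0        axial       -14
HL       (HL)13-          1   0   0    1   11.21    axial       -13
H2L      (H2L)12-         2   0   0    1   22.78    equatorial  -12
H3L      (H3L)11-         3   0   0    1   34.22    equatorial  -11
H4L      (H4L)10-         4   0   0    1   43.96    equatorial  -10
H5L      (H5L)9-          5   0   0    1   52.58    equatorial  -9
H6L      (H6L)8-          6   0   0    1   59.41    equatorial  -8
H7L      (H7L)7-          7   0   0    1   64.91    equatorial  -7
H8L      (H8L)6-          8   0   0    1   68.79    equatorial  -6
K5HL     [K5(HL)]8-       1   5   0    1   23.68    axial       -8
K4H2L    [K4(H2L)]8-      2   4   0    1   32.54    axial       -8
K3H4L    [K3(H4L)]7-      4   3   0    1   49.406   equatorial  -7
K2H5L    [K2(H5L)]7-      5   2   0    1   56.40    equatorial  -7
KH6L     [K(H6L)]7-       6   1   0    1   61.99    equatorial  -7
KH7L     [K(H7L)]6-       7   1   0    1   66.99    equatorial  -6
MgK4L    [MgK4L]8-        0   4   1    1   22.4     axial       -8
MgK4HL   [MgK4(HL)]7-     1   4   1    1   32.81    axial       -7
MgK3H2L  [MgK3(H2L)]7-    2   3   1    1   40.88    axial       -7
MgK3H3L  [MgK3(H3L)]6-    3   3   1    1   49.22    equatorial  -6
MgK2H4L  [MgK2(H4L)]6-    4   2   1    1   55.56    equatorial  -6
MgKH5L   [MgK(H5L)]6-     5   1   1    1   61.68    equatorial  -6
MgKH6L   [MgK(H6L)]5-     6   1   1    1   66.71    equatorial  -5
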