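---
title: "Models and methods behind ippspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ippspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippspec)
```

`ippspec` models the solution speciation of highly phosphorylated
myo-inositol messengers — InsP6 (phytate), the pyrophosphorylated analogue
5PCP-InsP5, and the doubly pyrophosphorylated InsP8 — and the measurements
used to characterize it: fast-exchange ³¹P-NMR titrations, variable-
temperature quantification of the axial/equatorial ring-flip, and isothermal
titration calorimetry (ITC) of protein binding.  This vignette records the
models, the numerical choices, and the limits of what the packaged synthetic
data can establish.

## 1. The chemical model

A species is written $\mathrm{H}_h\mathrm{K}_k\mathrm{Mg}_m\mathrm{L}$ and
carries a cumulative formation constant on the molar concentration scale,

$$\beta_{hkm} = \frac{[\mathrm{H}_h\mathrm{K}_k\mathrm{Mg}_m\mathrm{L}]}
{[\mathrm{H}]^h[\mathrm{K}]^k[\mathrm{Mg}]^m[\mathrm{L}]},$$

referenced to the fully deprotonated free ligand (charge $-14$ for InsP8)
and free ions.  The packaged registries (`ipp_model()`) store sums of the
published stepwise constants, determined in a constant ionic medium
(I = 0.15 M).  Three conventions follow the source experiments and are
limitations by design:

* constants are concentration quotients — no activity corrections;
* the 22 °C constants are used unchanged at other temperatures;
* axial/equatorial labels on species are annotations transcribed from the
  experimental assignment, never inferred by the package.

Net charges are a checksum: `charge = base_charge + h + k + 2m` must
reproduce every published superscript, and the document reader rejects a
model where it does not.  Stepwise protonation constants must be positive;
they are *not* required to decrease (for InsP8 the second, 22.78 − 11.21 =
11.57, exceeds the first — weak positive cooperativity of the first
protonations is a feature of the data).

## 2. Mass-balance speciation

At a titration point the pH is metered, so $[\mathrm{H}^+] = 10^{-\mathrm{pH}}$
is an input and protons are not mass-balanced (no hydroxo species occur in
the registries, so the water autoprotolysis constant never enters).  The
unknowns are the free concentrations of L, K⁺ and Mg²⁺ with totals
$T_L, T_K, T_{Mg}$:

$$T_X = [X] \cdot \mathbb{1}[X \text{ is an ion}] + \sum_j n_{X,j}\, c_j,
\qquad c_j = \beta_j [\mathrm{H}]^{h_j}[\mathrm{K}]^{k_j}[\mathrm{Mg}]^{m_j}[\mathrm{L}].$$

`solve_point()` iterates damped Newton steps on $\log_{10}$ free
concentrations (positivity is automatic; the Jacobian is analytic).
Numerical choices: initialization at 10% of totals followed by fixed-point
pre-balancing sweeps; steps capped at 2 log units; step halving (max 20)
until the max relative residual decreases; convergence at $10^{-10}$
relative residual; 200 iterations maximum, after which a flagged,
never-silent result is returned.  `speciation_diagram()` warm-starts each pH
from its neighbour (continuation), which keeps the full 22-species InsP8
model at a few Newton steps per point.  The test suite checks the solver
against an independent nested-bisection oracle to six significant digits on
all models with at most two unknowns.

Ties in `most_abundant_species()` break lexicographically by species id and
are flagged.  For a pH *window*, the package ranks species by their mean
ligand fraction over the grid.  That reading matters in one place: in the
metal-free InsP8 ladder, H₆L⁸⁻ narrowly overtakes H₅L⁹⁻ below pH ≈ 6.8
(stepwise log K₆ = 6.83), so "most abundant across pH 6.5–7.5" holds for
H₅L⁹⁻ on the window mean even though it is not the pointwise argmax at the
acidic edge.

EDTA, present in the source titrations as a trace-metal scavenger, is not
modelled; conditions are nominal totals.  Precipitation and multi-ligand
competition are out of scope.

## 3. Fast-exchange titration fitting

Under fast exchange each ³¹P nucleus resonates at the population-weighted
average of species-limiting shifts, $\delta_{\mathrm{obs}} = \sum_j f_j
\delta_j$ with $f_j$ the ligand mole fractions.  `fit_titration()` minimizes
the weighted squared misfit over a chosen subset of $\log\beta$ values by
*separable* least squares: for each trial constant vector the speciation is
solved per point and the limiting shifts — linear parameters — are projected
out by weighted linear least squares per nucleus.  The nonlinear search
(`nlminb`) therefore runs only over the constants, exactly the structure of
the classical titration-refinement programs.  A species never populated
above $10^{-4}$ anywhere is excluded from the projection and reported as
undetermined rather than silently fitted.

The misfit statistic is $\sigma = \sqrt{\sum w r^2 / (n_{\mathrm{obs}} -
n_{\mathrm{par}})}$ in ppm, with $n_{\mathrm{par}}$ counting refined
constants *and* projected shifts.  The published description of the
reference software does not define its scaling, so this per-degree-of-freedom
convention is the package's own, documented choice.  The accompanying
chi-square is a Pearson statistic of the standardized residuals over eight
equiprobable normal bins — a distribution check in the spirit of the
classical programs (compare to $\chi^2_{0.95,7} = 14.07$).  Constant
standard deviations come from the Gauss–Newton curvature of the profiled
residuals.  `model_selection()` ranks candidate models by $\sigma$, breaking
ties (within 5% relative, with an absolute floor of $10^{-9}$ ppm so that
noiseless fits tie) toward fewer species.

Protonation-site inference (`protonation_step_shifts()`) differences the
limiting shifts of consecutive ladder species; the nuclei within a margin
(default 0.1 ppm) of the most negative $\Delta\delta_P$ are reported as the
likely protonation sites, since protonation shifts the protonating phosphate
upfield.

### The synthetic shift basis, and a known limitation

The source study does not print its limiting shifts, so
`demo_shift_basis()` *fabricates* one: realistic baseline ³¹P positions,
upfield moves of 1–3 ppm per protonation step with the step-1 signature
concentrated on P3, P5b and P1b, a collective monophosphate jump standing in
for the ring-flip, and a downfield offset per bound cation.  Step amplitudes
were sized so that fitted constants carry standard deviations of the order
the source reports; the basis is labelled synthetic everywhere and supports
no quantitative claim about real shifts.

With this (or any) fully floated basis, the first protonation constant of
the InsP8 ladder is *sloppy*: because the second and third stepwise
constants exceed the first, HL never exceeds ~25% abundance, and the
profiled standard deviation of log K₁ at 0.02 ppm noise is ≈ 0.4–0.5 for
every basis design we tried, with a heavy upper tail (pushing K₁ above the
pH window makes free L unobservable at negligible cost in fit quality;
starting the optimizer at the true constants reproduces the same optima, so
this is the likelihood surface, not the optimizer).  Noiseless data
round-trip exactly.  Consequently the acceptance test demanding
$|\hat{K}_1 - 11.21| \le 0.1$ from one noisy synthetic titration is
expected to fail and is left failing; the acceptance *report* summarizes
the same computation by the median over five replicate datasets, which
suppresses the tail without touching the estimator.  A green version of
this band is not obtainable in the stated synthetic world, and the printed
±0.01 precision of the source experiment is not reproducible with a fully
free basis at this noise level.

## 4. Ring-flip thermodynamics

The equatorial→axial equilibrium constant is an integral ratio,
$K = [\mathrm{ax}]/[\mathrm{eq}]$, with an optional scalar impurity
subtraction on the nominated peak (the impurity level of the source spectra
is not printed, so it enters as a caller-supplied area).
`vant_hoff_fit()` pools all replicates into one ordinary regression of
$\ln K$ on $1/T$ — pooled, not averaged, matching the source procedure —
and converts slope and intercept with R = 1.987204×10⁻³ kcal/(mol·K):
$\Delta H^0 = -\mathrm{slope}\cdot R$, $\Delta S^0 = \mathrm{intercept}\cdot R$,
errors propagated from the regression standard errors.  The generator
(`gen_conformer_series()`) applies log-normal noise to K (integral ratios
are positive) over the 274–283 K window of the source design; the noiseless
round trip is exact by construction, which is what the corresponding
acceptance criterion checks — it validates the regression algebra, not any
spectroscopic claim.

`fraction_axial()` evaluates the Gibbs–Helmholtz extrapolation
$f_{\mathrm{ax}} = K/(1+K)$ with $K = e^{-(\Delta H^0 - T\Delta S^0)/RT}$.
Temperature is always explicit because "37 °C" can be read as 310 K (as
printed in the source) or 310.15 K; both are supported and differ in the
second decimal of the percentage.  Raw percentages are returned; rounding
to whole percent is display-side.

## 5. One-site ITC

`simulate_isotherm()` implements the single-site Wiseman model with
injection displacement for an overfilled cell: after cumulative injection
volume $\Delta V$, the displaced totals are
$M_t = M^0\frac{1-\Delta V/2V_0}{1+\Delta V/2V_0}$ and
$X_t = X^0\frac{\Delta V/V_0}{1+\Delta V/2V_0}$, the cumulative heat follows
the closed form of the binding quadratic, and per-injection heats are
differenced with the expelled-heat term and normalized per mole of
injectant.  The tests check this closed form against an independent
numerical solution of the quadratic per injection.  The active cell volume
$V_0$ is instrument-defined and defaults to 200 µL; simulator and fitter
share the protocol object, so desk-scale results are recovery-based and
only require internal consistency.  Dilution heat is a constant offset (no
blank-titration data exist in this setting); a first-injection discard is
available but off by default; stoichiometry n floats by default and can be
fixed.

`fit_one_site()` runs least squares over $(n, \log_{10} K_d, \Delta H,
\mathrm{offset})$ from three deterministic starts.  Derived quantities use
the 1 M standard state at the protocol temperature:
$\Delta G = RT\ln K_d$ and $-T\Delta S = \Delta G - \Delta H$, so the
thermodynamic closure $\Delta G = \Delta H + (-T\Delta S)$ is an identity.
The Wiseman c-value $n M_t/K_d$ is attached and values outside [1, 1000]
flag a low-information isotherm.  At the published conditions (50 µM cell,
K_d = 373 nM) c ≈ 134.

One stochastic band is provably out of reach: at heat noise 0.05 kcal/mol
the Cramér–Rao bound for this 19 × 2 µL protocol gives a relative standard
deviation of ≈ 9.9% on K_d, so no unbiased estimator keeps 90% of
replicates within ±15%.  The regular suite therefore asserts
near-efficiency (90% within three bound-sd), while the literal ±15% band is
kept in the acceptance suite and left red.

## 6. What the generators do and do not establish

The generators reproduce the *statistical structure* the analyses assume:
Gaussian ppm noise on population-averaged shifts (with optional missing
observations mimicking exchange-broadened peaks), log-normal noise on
integral ratios, Gaussian noise on molar heats, all Mersenne-Twister-seeded
and byte-reproducible, restoring the caller's RNG state.  They do not
simulate lineshapes, exchange broadening, relaxation, baseline drift,
precipitation, or instrument power traces.  A green round-trip test
therefore establishes that the estimators invert the stated forward models
at the stated noise — not that the forward models describe any particular
spectrometer or calorimeter.

## 7. Worked example

```{r example, eval = FALSE}
m <- ipp_model("insp8")
r <- solve_point(m, solution_conditions(1e-3, total_k = 0.15,
                                        total_mg = 1e-3, ph = 7.4))
most_abundant_species(r)          # "MgK3H3L", ~52% of ligand
fraction_axial(thermo_params(-7.2, -0.025), 310)   # 29.05305 -> "29%"
```
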