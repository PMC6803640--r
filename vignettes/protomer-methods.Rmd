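---
title: "Models and methods behind protomer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protomer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomer)
```

`protomer` packages the quantitative layers used to decide whether a small
protein is monomeric and how it binds a peptide target: surface plasmon
resonance (SPR) kinetics under a bivalent-analyte scheme, structure-derived
hydrodynamic metrics, native mass-spectrometry arithmetic, and trajectory
flexibility analysis. This vignette explains each model, the assumptions
behind it, the tunable parameters, and the numerical choices, in the
package's own terms.

## The bivalent-analyte kinetic model

An analyte `A` (a peptide, at molar concentration) flows over a surface
carrying an immobilized ligand `L` (a protein, in response units, RU). The
1:1 Langmuir scheme often fails for such systems: once a 1:1 complex `AL`
has formed, the bound peptide can recruit a *second* immobilized protein,
bridging two ligands into `AL2`. The scheme is

$$A + L \rightleftharpoons AL \quad (k_{a1}, k_{d1}), \qquad
  AL + L \rightleftharpoons AL_2 \quad (k_{a2}, k_{d2}),$$

with rate equations (all species in RU; `ka1` in M⁻¹s⁻¹ because the first
step consumes solution analyte, `ka2` in RU⁻¹s⁻¹ because the second couples
two surface species):

$$\begin{aligned}
dL/dt &= -(k_{a1} A L - k_{d1}\,AL) - (k_{a2}\,AL\,L - k_{d2}\,AL_2)\\
dAL/dt &= (k_{a1} A L - k_{d1}\,AL) - (k_{a2}\,AL\,L - k_{d2}\,AL_2)\\
dAL_2/dt &= k_{a2}\,AL\,L - k_{d2}\,AL_2
\end{aligned}$$

with `L(0) = Rmax`, `AL(0) = AL2(0) = 0`. The combination
`L + AL + 2·AL2` is conserved exactly: each bridged complex ties up two
ligands.

**The observable.** Instrument response tracks bound analyte mass. The
package takes `R(t) = AL + AL2`: one analyte contributes its mass once,
bridged or not. This is the standard bivalent-analyte readout and is
consistent with the mixed units of the rate constants; it is a modelling
choice the package documents rather than a measured fact, since SPR
instruments do not report species separately.

**Avidity.** Two affinities summarize the scheme. `KD_app1 = kd1/ka1`
(function `kd_app1()`) describes only the first binding event. The
steady-state analysis (`steady_state_fit()`) fits the saturation hyperbola
`Req(C) = Rmax_eq·C/(C + KD_appTOT)` to equilibrium responses; because the
bridging step stabilizes bound analyte, `KD_appTOT` can differ from
`KD_app1` by an order of magnitude. When the measurement error is relative
(constant CV), pass `weights = 1/response^2` to make the least-squares fit
match the noise model.

### Numerics

* Integration uses an adaptive Dormand–Prince 5(4) method written in C++
  (no ODE-solver package is required), with relative tolerance `1e-8` and
  absolute tolerance `1e-10` RU. At these settings the conservation defect
  `|L + AL + 2·AL2 − Rmax|` stays below `1e-6·Rmax` on every test problem,
  which is the invariant the tests enforce.
* A step-count ceiling (about 5000 steps per simulated second) converts
  pathologically stiff parameter proposals into a classed
  `protomer_integration_failure` instead of a hung fit.
* Global fitting (`spr_fit()`) shares `ka1, ka2, kd1, kd2, Rmax` across all
  curves of a titration and minimizes the summed squared residuals.
  Parameters are optimized as logarithms (they are positive and span
  decades): Nelder–Mead (800 iterations) followed by a BFGS polish, from 5
  starting points — the default guess
  (`ka1 = 1e4, ka2 = 1e-3, kd1 = 0.1, kd2 = 0.01, Rmax = max(R)`) plus four
  seeded log-uniform perturbations within half a decade. A soft box ±4
  decades around the starting guess keeps the search out of stiff regions
  no plausible SPR experiment occupies. Non-convergence is reported via the
  `converged` flag, not an exception; all-zero data raise a classed
  degenerate-fit error immediately.
* Standard errors come from the residual-variance-scaled inverse Hessian of
  the SSE at the optimum, delta-transformed back to the natural scale.
  Model discrimination (`anova()`) reports the SSE ratio and AIC difference
  between the Langmuir and bivalent fits, which is how "the data could not
  be fitted by a 1:1 model" becomes a number.
* A baseline offset per curve is available (`baseline = TRUE`) but off by
  default; the model includes no mass-transport step.

### The stated synthetic world

The generator defaults encode one fixed, realistic experiment rather than
free dials: two-minute injections, 200 s dissociation, 1 s sampling;
eight two-fold dilutions from 30 µM (down to 0.23 µM); `Rmax = 500 RU`
(a mid-level immobilization for a ~20 kDa ligand — not a measured value);
additive homoscedastic Gaussian noise, σ = 1 RU unless stated, with an
optional linear drift. Under this world, noise-free refits recover the
generating constants to better than 0.1% and σ = 1 RU refits recover each
constant with median error well under 10% — those recoveries are computed
by the test suite, not quoted from anywhere.

What the generator does **not** emulate: injection spikes, bulk
refractive-index jumps, mass-transport limitation, surface heterogeneity,
or baseline decay of the immobilized ligand. A green recovery test
therefore establishes the fitter against the model's own assumptions, not
against every artifact of real instrument exports.

## Hydrodynamic and surface metrics

* **Radius of gyration** — mass-weighted by default (`weighting =
  "uniform"` available), reported in nm from Å coordinates. Verified
  against the two-point symmetry case and the solid-sphere limit
  `Rg = sqrt(3/5)·R`.
* **Solvent-accessible surface** (`sasa()`) — Shrake–Rupley with a
  deterministic golden-spiral point set, probe 1.4 Å, 960 points per atom
  by default (doubling the count moves totals by < 0.5% on the fixtures).
  Van der Waals radii follow Bondi's compilation. The hydrophobic /
  hydrophilic split assigns C and S to the hydrophobic class and N, O, P
  (and polar hydrogens, when present) to the hydrophilic class; PDB files
  are read without hydrogens by default, giving united-atom areas. The
  split is exact by construction: the two classes partition the atoms.
  Exactly coincident duplicate atoms contribute zero marginal area.
* **Stokes–Einstein** — `d = kB·T/(3π·η·D)`, defaults 310.15 K and water
  viscosity at 37 °C (6.913e-4 Pa·s).
* **DLS cumulants** (`dls_cumulant_diameter()`) — second-order cumulant fit
  `ln(g2−1) = ln B − 2Γτ + µ2τ²`, weighted by `(g2−1)²` so the
  noise-amplified late lags carry little weight, restricted to lags before
  the signal decays below `exp(-3)` of its peak. `D = Γ/q²`, with `q` from
  a 173° backscatter geometry, 633 nm laser, n = 1.330 — typical
  Zetasizer-class settings, chosen as documented defaults because such
  instrument constants are rarely printed in papers. `PDI = µ2/Γ²`.
* **SEC calibration** — `log10(MW)` linear in elution volume, by ordinary
  least squares; predictions outside the calibrated range are computed but
  warn about extrapolation. Apparent `MW_SEC` from SEC reflects the Stokes
  radius and solvation, not mass alone — which is exactly why a
  hydrophobic monomer can masquerade as a dimer, and why this package
  computes independent estimates.

## Native-MS and cross-linking arithmetic

Charge-series deconvolution searches every *consecutive* charge assignment
in the window (charges descending as m/z ascends), computes the implied
neutral masses `M_i = z_i·(m/z_i − 1.00728)`, and keeps the assignment with
the smallest standard deviation; the result is the intensity-weighted mean.
A dispersion above 0.2% of the mass means no consistent series and raises a
classed error rather than returning a number. On synthetic series the
inverse is exact; with m/z rounded to integers (as printed in papers) the
recovered mass stays within 0.1%.

Average (not monoisotopic) masses are used throughout, appropriate at the
intact-protein scale. The DSBU bridge adds 196.1 u per fully reacted
linker (configurable); a one-side-reacted, hydrolyzed linker carries one
extra water (+18.011 u). Peptide masses come from a bundled standard
average residue-mass table plus water, with optional terminal
modifications (acetyl +42.037, amide −0.985).

One documented wrinkle: reproducing a printed 1:1 complex mass of a
synthesis-acetylated peptide can require treating the N-terminus as *free*
— the modification flags are exposed precisely so the user can state the
convention instead of having one silently imposed. The package's default
reproduction of the printed value uses a free N-terminus and amidated
C-terminus.

## Flexibility

`kabsch_superpose()` computes the optimal least-squares rigid superposition
by SVD with the determinant correction (reflections excluded); collinear
selections are rejected as degenerate. The test oracle for it is Horn's
closed-form quaternion eigenvalue solution — an independent derivation of
the same optimum.

`rmsf_per_residue()` reports, per Cα,
`RMSF_i = sqrt(mean_t |r_i(t) − r_i,ref|²)` in nm, after per-frame
superposition on the Cα selection (default on). The reference is the
supplied equilibrated structure when given, else the first frame;
`reference = "mean"` measures about the time-average instead, which by
variance decomposition is a lower bound on any fixed-reference profile.
Note that superposition absorbs six rigid degrees of freedom, so fitted
profiles of pure-noise trajectories sit slightly below the unfitted
`σ·√3` expectation (by a factor `sqrt(1 − 6/(3N))` for N residues);
invariance checks therefore compare fitted against fitted.

The synthetic trajectory generator draws all fluctuation noise before any
rigid-motion contamination, so a given seed produces the identical
displacement field with contamination on or off — that is what makes the
rigid-motion-invariance test exact rather than statistical.

## Degenerate inputs and error classes

All precondition violations and analysis failures raise classed conditions
(`protomer_domain_error`, `protomer_degenerate_fit`,
`protomer_unidentifiable_fit`, `protomer_integration_failure`,
`protomer_no_consistent_series`, `protomer_fit_failure`,
`protomer_invalid_sequence`, `protomer_insufficient_data`) so callers can
distinguish "bad input" from "data cannot identify the model" without
string matching.

## Known limitations

* No mass-transport or conformational-change SPR models; no surface
  heterogeneity. Real exported sensorgrams with those artifacts will fit
  with structured residuals.
* DLS is reduced by cumulants only; multimodal intensity distributions
  (CONTIN-style inversion) are out of scope, and the bimodal behaviour of
  the cumulant mean rate is characterized, not resolved.
* Bead-model hydrodynamic diameters (HydroPro-style) are not computed;
  such values are treated as external references.
* The PDB reader handles standard fixed-width ATOM/HETATM records (first
  model, or all models via `read_pdb_trajectory()`); it is not a general
  mmCIF/malformed-file parser.
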