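---
title: "Two-state exchange analysis of CEST Z-spectra: models, kernels and fitting choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state exchange analysis of CEST Z-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestfit)
```

## The physical model

Chemical exchange saturation transfer (CEST) detects sparsely populated,
"invisible" protein conformations. A weak radio-frequency field of strength
$\nu_1$ (Hz) is applied for a time $T_\mathrm{sat}$ at a series of carrier
positions $\delta_\mathrm{sat}$; whenever the carrier sits near the
resonance of an exchanging minor state B, saturation is transferred through
exchange to the visible ground state A and the observed ground-state signal
drops. The Z-spectrum — normalized intensity $I/I_0$ versus carrier
position — shows a deep dip at the ground-state shift $\delta_A$ and a
shallow one at the minor-state shift $\delta_A + \Delta\delta$.

`cestfit` models two-state exchange $A \rightleftharpoons B$ with total
rate $k_\mathrm{ex} = k_{AB} + k_{BA}$ and minor population
$p_B = k_{AB}/k_\mathrm{ex}$. The magnetization obeys the Bloch–McConnell
equations. With the RF field along $+x$ of the rotating frame and resonance
offsets $\Omega_S = 2\pi(\delta_S - \delta_\mathrm{sat}) \cdot
\nu_\mathrm{Larmor}$ (ppm × MHz = Hz), each state $S$ with partner $S'$
evolves as

$$
\begin{aligned}
\dot M_x^S &= -(R_{2,S}+k_{SS'}) M_x^S - \Omega_S M_y^S + k_{S'S} M_x^{S'}\\
\dot M_y^S &= +\Omega_S M_x^S - (R_{2,S}+k_{SS'}) M_y^S - \omega_1 M_z^S + k_{S'S} M_y^{S'}\\
\dot M_z^S &= +\omega_1 M_y^S - (R_{1,S}+k_{SS'}) M_z^S + k_{S'S} M_z^{S'} + R_{1,S}\, p_S,
\end{aligned}
$$

where the final constant term makes $M_z$ relax toward the equilibrium
population $p_S$ rather than toward zero. Absorbing that constant into an
augmented first element fixed at 1 turns the generator into the 7×7 matrix
built by `bm_generator()`, with state layout
$[1, M_x^A, M_y^A, M_z^A, M_x^B, M_y^B, M_z^B]$.

**Conventions.** $\Delta\delta \equiv \delta_B - \delta_A$ is signed, so a
negative value puts the minor dip upfield of the ground dip. Offsets in
input files are absolute carrier positions in ppm. The initial condition is
thermal equilibrium, $[1, 0,0,p_A, 0,0,p_B]$: no transverse magnetization,
both states polarized. The reference intensity is the $T_\mathrm{sat}=0$
experiment, which returns exactly $p_A$, so the reported quantity is
$M_z^A(T_\mathrm{sat})/p_A$ and far-off-resonance intensities sit at 1.
These conventions make the simulated spectra look like measured Z-spectra
(baseline at unity) and make the signed shift list of a typical assignment
table directly usable.

## The three kernels

*Matrix* (`zspec_matrix()`): one matrix exponential of the 7×7 generator
per offset, the reference numerical solution. Its contract is agreement
with an independent fine-step ODE integration of the same equations, which
the test suite enforces to better than $10^{-6}$ in intensity.

*Analytical* (`zspec_baldwin()`): the same constant-irradiation problem
solved in closed form through the spectral decomposition of the homogeneous
6×6 exchange generator $L$,
$$
M(t) = M_\mathrm{ss} + \mathrm{Re}\!\left[V e^{\Lambda t} V^{-1}
(M_0 - M_\mathrm{ss})\right],\qquad M_\mathrm{ss} = -L^{-1} b,
$$
with $b$ the equilibrium-recovery drive. One eigendecomposition and two
6×6 solves per offset replace the 7×7 exponential; in this implementation
that is roughly an order of magnitude cheaper inside the fitting loop,
which is the reason high-throughput CEST analysis is built on
rotating-frame (R1ρ) theory in the first place. The slowest-decaying
eigenmode of $L$ — selected by overlap of its eigenvector with the tilted
effective-field direction — is exposed as the effective rotating-frame
relaxation rate by `r1rho_baldwin()`; in the no-exchange limit it reduces
to the textbook $R_1\cos^2\theta + R_2\sin^2\theta$ with
$\tan\theta = \omega_1/\Omega$ and it tends to $R_1$ far off resonance.

A simpler projection formula, $I = \cos^2\theta\, e^{-R_{1\rho}
T_\mathrm{sat}}$, is common in the spin-lock literature. We examined it and
rejected it for Z-spectra under these conditions: it ignores the
$R_1$-driven return to equilibrium (its far-off-resonance baseline is
$e^{-R_1 T_\mathrm{sat}} \approx 0.55$ at $R_1 = 1.5\,\mathrm{s^{-1}}$,
$T_\mathrm{sat} = 0.4$ s, where the true baseline is 1) and it drops the
damped nutation transients that are visible on dip shoulders at a 100 Hz
field, which alone contribute intensity errors of a few times $10^{-2}$.
The spectral solution costs the same order of work, is exact, and keeps the
two exchange kernels within their mutual $10^{-2}$ agreement contract with
margin to spare. A corollary of including recovery exactly: at
$T_\mathrm{sat}=0$ the analytical kernel returns 1 (continuity with the
matrix kernel), and on-resonance intensities equal the small exact steady
state rather than exactly zero.

*No-exchange control* (`zspec_noex()`): exact single-spin Bloch evolution
(augmented 4×4, including $R_1$ recovery). It answers "does this profile
need exchange at all?" — its reduced chi-square on exchange-bearing data is
an order of magnitude worse than the exchange kernels, which is the
expected and tested behaviour. We deliberately use the full off-resonance
single-spin solution rather than an on-resonance shortcut, so the control
is wrong only for the physics it omits (exchange), never for the physics it
shares.

## B1 inhomogeneity

The RF field varies over the sample volume. `apply_b1_inhomogeneity()`
models $\nu_1$ as Gaussian with fractional standard deviation
`b1_frac_sigma`, evaluates the kernel on an equally spaced grid of
`b1_grid_points` (default 11) field values spanning $\pm 2\sigma$, and
averages with Gaussian weights renormalized to sum to one (truncation
correction). Zero width or a single point reproduces the nominal profile
bit-exactly, and 11 points agree with 101 points to better than $10^{-3}$
in intensity at $\sigma = 10\%$, so the default grid is converged. The
width is an instrument property with no universal value; it defaults to 0
(off) and is a user parameter.

## Fitting

Profiles must span at least two distinct RF field strengths: at a single
field, $k_\mathrm{ex}$, $p_B$ and $R_{2,B}$ form a classic degenerate
triplet. `joint_fit()` refuses single-field exchange fits with an explicit
error instead of returning an unidentifiable answer.

The objective is $\sum_i \left[(I_i^\mathrm{obs} -
I_i^\mathrm{calc})/\sigma_i\right]^2$ over all points of all profiles.
With `share_kinetics = TRUE` (default) one $(k_\mathrm{ex}, p_B)$ pair is
common to all residues — appropriate for a single global process — while
$\delta_A$, $\Delta\delta$, $R_{1,A}$, $R_{2,A}$, $R_{2,B}$ are
per-residue. $R_{1,B}$ is tied to $R_{1,A}$ because CEST data at these
conditions carry essentially no information about it. We fit
$(k_\mathrm{ex}, p_B)$ rather than $(k_{AB}, k_{BA})$: the former pair is
better conditioned and maps onto the degeneracy structure of the problem;
the one-way rates are reported as derived quantities with delta-method
uncertainties.

**Initialization** is automatic and two-stage. Dips are detected on the
lowest-B1 profile (weak fields give the narrowest dips) after a 3-point
running mean — real dips span several grid points, single-point noise
minima do not — against a robust baseline (median of the upper intensity
quartile), with a depth threshold of 3 times the median point uncertainty.
The deepest dip seeds $\delta_A$, the second $\Delta\delta$. Kinetics come
from a coarse grid search ($k_\mathrm{ex} \in \{50, 100, 200, 400, 800,
1600\}$ s⁻¹ × $p_B \in \{0.005, 0.01, 0.02, 0.05, 0.1\}$) scored with the
analytical kernel at typical backbone ¹⁵N relaxation values
($R_1 = 1.5$, $R_2 = 10$ s⁻¹).

When exchange is fast or $|\Delta\delta|$ small, the minor dip coalesces
with the ground dip and no secondary minimum exists even in noiseless data;
the start then falls back to $|\Delta\delta| = 2$ ppm and the *sign* is
chosen by running the kinetics grid for both mirror signs and keeping the
better-scoring one. This matters: the mirror solution $(-\Delta\delta)$ is
a genuine local minimum of the objective, and a wrong-signed start can drag
the global kinetics with it. The fallback is flagged in the result and the
report.

**Refinement** uses bound-constrained Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), the standard bound-respecting trust-region-family
optimizer available in R. Default bounds: $k_\mathrm{ex} \in [1, 10^5]$
s⁻¹, $p_B \in [10^{-4}, 0.5]$, $\Delta\delta \in [-30, 30]$ ppm,
$\delta_A$ within the residue's data window, $R_1 \in [0.05, 10]$,
$R_2 \in [0.5, 200]$ s⁻¹. Convergence at the iteration cap (200) is
flagged, not hidden.

**Uncertainties** come from the covariance $(J^\top J)^{-1}$ of the
weighted problem and, when `mc_iterations > 0`, from parametric Monte
Carlo: synthetic datasets are the best-fit curves plus Gaussian noise of
the per-point $\sigma$, each refit from the best-fit start, and the spread
over iterations is reported. Refits ending on a bound are retained but
counted, with a warning flag past 50%. For well-conditioned fits the two
error estimates agree within a factor of two (tested). When input files
carry no uncertainty column, $\sigma$ is estimated as the standard
deviation of the intensities at the 20% of offsets farthest from all
detected dips — chi-square needs a scale, and the dip-free baseline
carries the point noise.

## The synthetic benchmark

`validation_spec()` encodes the study conditions used throughout the test
suite: five residues spanning slow to fast-intermediate regimes
($\delta_A$ = 118.0, 110.0, 115.0, 120.0, 125.0 ppm; $\Delta\delta$ =
−5.0, −1.0, +2.0, +2.0, −3.0 ppm), $k_{AB} = 15$ s⁻¹, $k_{BA} = 285$ s⁻¹
(so $k_\mathrm{ex} = 300$ s⁻¹, $p_B = 0.05$), ¹⁵N Larmor frequency 80.12
MHz, $T_\mathrm{sat} = 0.4$ s, fields of 10 and 100 Hz, and 2% Gaussian
errors on both the intensities (per point) and the RF field calibration
(one multiplicative draw per profile). The generated profiles carry the
*nominal* field, so the fit must absorb the calibration error — exactly
the robustness the dual-field design is meant to deliver. Values the
benchmark needs but that are not fixed by the study design were chosen
once on physical grounds and not revisited: $R_1 = 1.5$ s⁻¹ and $R_2 =
10$ s⁻¹ are typical backbone ¹⁵N values at this field, and the offset grid
(104–130 ppm in 0.25 ppm steps, 105 points per profile, 1050 points in a
full fit) covers every resonance with ≥ 2 ppm margin and resolves the
10 Hz dips. For noiseless variants the σ column is floored at $10^{-3}$ so
chi-square weighting stays defined; weights are then uniform and parameter
recovery is unaffected.

What the generator emulates — and what it does not. It produces Gaussian
point noise, field-calibration error, and exact two-state line shapes. Real
spectra add baseline distortions, peak overlap in the source spectra,
temperature drift, scalar-coupling effects and possibly more than two
states. Passing the benchmark therefore demonstrates correctness of the
solver and estimator under the stated error model, not robustness to every
experimental pathology.

## Numerical choices and degenerate inputs

- Matrix exponentials and eigendecompositions use Armadillo (`expmat`,
  `eig_gen`). If the 6×6 eigensystem is ill-conditioned at some offset
  (e.g. exactly degenerate eigenvalues at $\omega_1 = 0$), the analytical
  kernel falls back to the exponential route for that offset, so the two
  kernels agree by construction in the corner cases.
- Ties in dip depth are broken by detection order; minima closer than
  three grid steps are merged, keeping the deeper.
- Duplicate offsets in input files are averaged with a warning; malformed
  numerics are rejected with the line number rather than coerced.
- Intensities outside $[-1.5, 1.5]$ are rejected at parse time: Z-spectra
  are normalized quantities and values outside that window indicate a
  wrong normalization, not exotic physics.

## Known limitations

Two-state exchange only; constant-phase rectangular saturation (no shaped
or DANTE pulses); no scalar-coupling evolution; no joint analysis across
static fields; model comparison across kernels is by reduced chi-square,
not by automated information criteria. The web-oriented conveniences of
interactive residue picking are replaced by `detect_dips()` plus explicit
residue selection in the configuration.

## Problem sizes used in the tests

Unit tests run on a two-residue, coarser-grid variant of the benchmark so
that a full joint fit takes a couple of seconds; the acceptance suite runs
the full five-residue benchmark (1050 points, 27 parameters) with all
three kernels, an independent-integrator cross-check of the matrix kernel,
and a 12-iteration Monte-Carlo error estimate. These sizes were chosen so
the whole suite completes in a few minutes on one core while still
exercising every code path at the benchmark's full dimensionality.
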