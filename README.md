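# cestfit

Two-state chemical exchange analysis of CEST NMR Z-spectra.

Proteins often function through "invisible" excited states — transient
conformations populated at a few percent that X-ray crystallography and
cryo-EM miss. Chemical Exchange Saturation Transfer (CEST) NMR detects
them: a weak RF field of strength ν₁ saturates the minor-state resonance
for a time T<sub>sat</sub>, exchange carries the saturation to the visible
ground state, and the ground-state signal dips. `cestfit` turns the
resulting Z-spectra (normalized intensity I/I₀ versus saturation-carrier
position, ppm) into the kinetic and structural parameters of the exchange
process: the exchange rate k<sub>ex</sub> = k<sub>AB</sub> + k<sub>BA</sub>,
the minor-state population p<sub>B</sub>, the chemical-shift differences
Δδ = δ<sub>B</sub> − δ<sub>A</sub> (signed), and the relaxation rates
R₁ and R₂ of both states.

The package is aimed at NMR spectroscopists and methods developers who
want a scriptable, fully testable CEST engine: three forward kernels, a
Gaussian correction for RF-field (B1) inhomogeneity, joint
multi-field least-squares fitting, Monte-Carlo error estimation, plain-text
I/O, and a seeded synthetic benchmark generator.

## The model

Magnetization of the exchanging pair A ⇌ B under constant irradiation
obeys the Bloch–McConnell equations; with offsets
Ω<sub>S</sub> = 2π(δ<sub>S</sub> − δ<sub>sat</sub>)·ν<sub>Larmor</sub> and
RF field ω₁ = 2πν₁ along +x, and with longitudinal relaxation driving
M<sub>z</sub> toward the equilibrium populations, the generator is the
augmented 7×7 matrix over `[1, Mx_A, My_A, Mz_A, Mx_B, My_B, Mz_B]`.
Three kernels predict I/I₀ from it:

- **matrix** — matrix exponential of the 7×7 generator per offset; the
  reference numerical solution.
- **baldwin** — the closed-form constant-irradiation solution via spectral
  decomposition of the homogeneous 6×6 exchange generator
  (M(t) = M<sub>ss</sub> + V e<sup>Λt</sup> V⁻¹(M₀ − M<sub>ss</sub>));
  roughly an order of magnitude faster inside the fitting loop and exact.
  The slowest-decaying eigenmode is exposed as the effective rotating-frame
  relaxation rate R<sub>1ρ</sub> (`r1rho_baldwin()`).
- **noex** — exact single-spin Bloch evolution, the no-exchange negative
  control.

Because k<sub>ex</sub>, p<sub>B</sub> and R<sub>2,B</sub> are degenerate at
a single RF field strength, `joint_fit()` requires profiles at two or more
distinct fields (e.g. 10 and 100 Hz) and fits them simultaneously —
globally shared (k<sub>ex</sub>, p<sub>B</sub>) plus per-residue shifts and
relaxation rates, refined by bound-constrained Levenberg–Marquardt from
automatic dip-detection and grid-search starting values.

## Worked example

Simulate the five-residue, two-field benchmark (2% intensity noise, 2%
per-profile B1 calibration error, generating rates k<sub>AB</sub> = 15,
k<sub>BA</sub> = 285 s⁻¹) and fit it:

```r
library(cestfit)

ds  <- generate_dataset(validation_spec(seed = 42))
fit <- joint_fit(ds$profiles, ds$acquisition,
                 fit_spec(method = "baldwin", seed = 42))
fit
#> Joint CEST fit (baldwin kernel): 1050 points, 27 parameters
#>   reduced chi-square: 1.005
#>   k_ex = 293 +/- 9.3 1/s, p_B = 0.05312 +/- 0.0018
#>   k_AB = 15.56 +/- 0.77 1/s, k_BA = 277.4 +/- 8.7 1/s
#>   flags: A2: no secondary dip; delta_delta start defaulted to -2 ppm ...

subset(fit$per_residue, param == "delta_delta")
#>    residue       param     value         se
#> 2       A1 delta_delta -4.975839 0.03475723
#> 7       A2 delta_delta -1.036145 0.04567004
#> 12      A3 delta_delta  1.944250 0.03664467
#> 17      A4 delta_delta  1.926781 0.04202245
#> 22      A5 delta_delta -2.942338 0.03742030
```

A reduced chi-square of ≈ 1 says the model accounts for the data within
its stated noise; the one-way rates and signed shift differences recover
the generating values within their uncertainties — including residue A2,
whose minor dip is coalesced with the ground dip and is flagged as having
started from the mirror-scored fallback. The 2% field-calibration errors
are *not* told to the fit (profiles carry the nominal ν₁), which is what
leaves the recovered rates a few percent off truth — the same robustness a
real dual-field experiment demands.

### Files and the command line

Profile files are plain text, whitespace- or comma-delimited (`#`
comments): `offset_ppm  intensity  [sigma]`, one file per residue per
field, bound together by a YAML configuration (see `?read_config`). The
thin CLI under `inst/cli/cestfit` drives the same functions:

```sh
cestfit simulate --out demo --seed 42
cestfit fit --config demo/config.yaml --method baldwin --out demo/results
cestfit validate --seed 42        # three-kernel comparison table
```

Every fit archives its configuration (`config_used.yaml`) and a content
hash into the output directory; re-running from the archive reproduces the
report byte-for-byte.

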