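---
title: "Measuring α-helix length by transition dipole strength: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring α-helix length by transition dipole strength: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdsir)
```

# The measurement model

A vibrational transition with dipole strength $|\mu|^2$ contributes to a
linear absorption spectrum in proportion to $|\mu|^2$ and to a 2D IR
spectrum in proportion to $|\mu|^4$. Dividing the 2D diagonal by the
linear OD therefore isolates $|\mu|^2$ up to instrument factors, which are
removed by measuring a calibrant of known dipole strength under identical
conditions and by normalizing out the pump envelope:

$$d(\omega) \;=\; \frac{|\Delta \mathrm{OD}_s(\omega,\omega)|}{\mathrm{OD}_s(\omega)}
\cdot \frac{\mathrm{OD}_c(\omega_{max})}{|\Delta \mathrm{OD}_c(\omega_{max},\omega_{max})|}
\cdot \frac{I_{pump}(\omega_{max})}{I_{pump}(\omega)} \cdot |\mu_{cal}|^2 .$$

N-methylacetamide serves as the calibrant: one uncoupled amide I′
oscillator, $|\mu_{cal}|^2 = 0.12\,\mathrm{D}^2$. The ratio construction
has two structural consequences that the test suite asserts exactly:
$d(\omega)$ is invariant under joint rescaling of
$\Delta\mathrm{OD}_s$ and $\mathrm{OD}_s$ (concentration and path length
cancel) and under global rescaling of the pump; and running the calibrant
as the sample returns $d(\omega_{max}) = |\mu_{cal}|^2$ to floating point.

Assumptions: parallel-polarization spectra collected at zero waiting time;
a diagonal that is dominated by the fundamental (bleach) lobe, with the
anharmonically red-shifted overtone far enough away not to contaminate it;
and a linear OD whose non-resonant background is removable by a smooth
baseline model. No polarization or waiting-time corrections are applied.

Vibrational delocalization grows with continuous structure, and because it
cannot bridge breaks between helices, the apparent TDS of an unresolved
multi-helix protein is set by the *longest* helix rather than a weighted
average. The calibration line is therefore inverted as a predictor of
maximum helix length only.

# Baseline estimation

`whittaker_smooth()` solves $(W + \lambda D^\top D)z = Wy$ with a sparse
Cholesky factorization (`Matrix`), where $D$ is the order-$d$ difference
operator. `airpls_baseline()` wraps it in the adaptive reweighting loop:
points above the current baseline get weight 0, points below get weight
$\exp(t\,|r_i|/m)$ with $m$ the total negative-residual mass, and the loop
stops when $m < \mathrm{tol}\cdot\sum|y|$.

Numerical choices:

- **`lam = 1e5`** by default for amide-I′-width bands on a ~1 cm⁻¹ grid:
  stiff enough to bridge a 20–30 cm⁻¹ band without sagging into it, soft
  enough to follow broad solvent backgrounds. It is a config parameter
  because no single value suits all grids.
- **`diff_order = 2`, `max_iter = 50`, `tol = 1e-3`** — conventional
  airPLS settings; all recorded in the output metadata.
- **Endpoint pinning**: the first and last weights are set to the maximum
  weight each iteration, preventing baseline droop when the spectrum is
  cropped close to the band.
- **Stall guard**: on noisy data the exponential weights can concentrate
  on the few most negative noise excursions, after which the baseline
  runs away below the data and the residual-mass test "converges" on a
  nonsense answer. The loop therefore also terminates — returning the
  previous iterate — once fewer than max(4, 5%) of points retain a
  negative residual; at that stage the baseline already hugs the lower
  noise envelope. This guard is what established implementations of the
  algorithm converged on as well, and without it the noisy recovery suite
  exhibits baseline failures an order of magnitude larger than the noise.
- Reaching `max_iter` is reported in metadata, not raised as an error.
- Degenerate inputs: all-zero weights are a singular system and an error;
  spectra shorter than `diff_order + 2` are rejected.

A consequence of the lower-envelope construction is a small negative bias
of the baseline on noisy data (≈1–2 noise SDs), hence a small positive
bias of corrected peak heights; at the signal-to-noise of the recovery
suites this stays well inside the stated tolerances.

# TDS extraction

- The diagonal slice takes $|\Delta\mathrm{OD}|$ at equal pump and probe
  frequency, interpolating linearly along the probe axis within each pump
  row; only the fundamental-lobe magnitude is used.
- $\omega_{max}$ of the calibrant is located on its baseline-corrected
  linear OD (smoother than the 2D diagonal); an argmax on the axis
  boundary means the band was not captured and is an error.
- All interpolation is linear, and no operation extrapolates: the working
  axis is always the intersection grid, anchored on the sample diagonal
  axis.
- **`od_floor_frac = 0.05`**: the ratio diverges as OD → 0, so points with
  OD below 5% of the maximum are masked (`NA`), not computed. Exposed in
  the interface because the right floor depends on the noise floor.
- `peak_tds()` reads $d$ at the argmax of the TDS spectrum inside an
  assignment window by default. Reading at the 2D diagonal maximum instead
  is available via `reference=`, mirroring the two defensible conventions
  for "the TDS at the amide I′ peak"; the default follows the TDS
  spectrum because that is the curve the value is read from.

# CD helicity

Mean residue ellipticity $[\theta] = \theta/(l\,C\,n)$ (mdeg, mm, mol/L)
is compared at 222 nm against the theoretical helix maximum
$[\theta]_H = -40000(1 - x/n) + 100\,T$. The end-effect constant defaults
to $x = 2.5$, appropriate for chains of roughly 8–23 residues. Negative
percent-helicity ratios (disordered line shapes) are clamped to zero for
reporting, with the raw ratio kept for diagnostics. Helical residue counts
are reported to 0.1 residue with half-up rounding, matching how such
values are conventionally printed; the [EAAAK]ₙ chain lengths are encoded
as 8, 13, 18, 23 for $n = 1..4$ (a 5-residue repeat plus termini) in the
built-in calibration table, and 222 nm is read by linear interpolation
when it is not a grid point.

# Calibration and inversion

`fit_calibration()` is ordinary least squares of TDS on helical residues
via `stats::lm`. Unweighted by default: replicate SDs are available and a
$1/\mathrm{sd}^2$ weighted fit is offered, but the calibration as used for
the reported predictions is a plain trendline, and with four points the
weights would let a single tight point dominate. The fit is free rather
than forced through $(0, 0.12)$ (the uncoupled-amide value): the free
intercept of the built-in table lands at 0.122 D² anyway, and forcing it
would understate the coefficient uncertainty. The [EAAAK]₂ abscissa is
the CD-derived 5.9 residues rather than the rounded 5.

`predict_helix_length()` inverts the line and propagates uncertainty to
first order (delta method) from the coefficient covariance plus an
optional measurement SD; with only four calibration points a bootstrap
would be theater. Out-of-range predictions are flagged
(`below_range`, `extrapolated`) rather than refused — extrapolating
moderately beyond the longest calibration peptide is precisely how long
helices are sized. `frequency_trend()` fits the frequency-vs-length line
with the same machinery but carries a permanent caveat: frequency is
unreliable for globular or membrane proteins, which is the reason TDS is
the predictor.

# What the synthetic generator does and does not emulate

Scenes compose unit-area Gaussian/Lorentzian/pseudo-Voigt amide I′ bands,
a polynomial-plus-broad-Gaussian baseline, a Gaussian pump envelope, and
i.i.d. Gaussian noise; every generator is a deterministic function of
(scene, seed), and the RNG state of the caller is left untouched. The 2D
spectrum is constructed by inverting the TDS ratio on the diagonal, with a
peak-pair template (negative fundamental, positive overtone shifted 16
cm⁻¹ along probe — a typical amide I′ anharmonicity) giving realistic
off-diagonal structure that the pipeline must ignore. The ground-truth
profile between overlapping bands is the OD-weighted mean of band TDS
values — the apparent value an unresolved pair would present.

Defaults chosen once, as realistic study conditions: random scenes use a
1540–1750 cm⁻¹ axis at 1 cm⁻¹, pump centered 1640 cm⁻¹ with 120 cm⁻¹
FWHM, 1–3 bands with centers 1615–1675 cm⁻¹, FWHM 15–30 cm⁻¹, peak OD
0.1–0.3, TDS 0.12–0.35 D², and smooth backgrounds up to ~0.15 OD. The
recovery suites run 50 such scenes noise-free (every band recovered within
2%) and 50 at SNR 50 on the linear OD, where the scene's main amide I′
mode is recovered within 10% for at least 95% of scenes; weak secondary
modes sit on a small OD denominator and are intrinsically noisier, which
is why experimental secondary-mode values are only read from clearly
resolved TDS peaks.

Not emulated: response-function line shapes (no nodal slant, no
polarization or orientational factors), waiting-time dynamics, coupling
cross peaks, correlated (1/f) baseline noise, and solvent absorption
lines. Passing recovery tests therefore demonstrates the correctness of
the inversion chain, not robustness to every artifact of measured
spectra.

# Degenerate inputs and tie-breaks

- Duplicate axis points are format errors, never averaged — silent
  averaging hides acquisition problems.
- Files without the expected unit-tagged header are rejected, not guessed.
- A single-point pump/probe overlap yields a degenerate length-1 diagonal
  slice (the one container allowed below the two-point minimum).
- `which.max` ties resolve to the lower wavenumber (first index),
  inherited deliberately from base R.
- Transmission must be strictly positive before taking logs; zero or
  negative values are domain errors, not `Inf`s.

# Known limitations

- The calibration inversion is only as good as its four-point line;
  the delta-method SE (~1 residue at the line's center) understates error
  far outside the calibrated range.
- airPLS assumes peaks are positive excursions on a smooth background;
  derivative-shaped artifacts (imperfect solvent subtraction) violate it.
- The 2D background handling is limited to what the diagonal ratio
  tolerates; no 2D surface baseline is attempted.
- β-sheet TDS values are reported but never inverted to strand counts: no
  monotone relation supports it.
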