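# tdsir

Transition dipole strength (TDS) analysis of two-dimensional infrared
(2D IR) spectra, for quantifying protein secondary structure — in
particular, predicting the length of the **longest α-helix** in a protein
from a single TDS value.

## The problem and the method

The amide I′ frequency of a deuterated protein backbone is an ambiguous
structure reporter: α-helices (1635–1655 cm⁻¹) overlap disordered
structures (~1645 cm⁻¹), and solvatochromic shifts in globular or membrane
proteins can cancel the structural redshift entirely. The transition
dipole strength |μ|² is not: vibrational delocalization across coupled
backbone amides grows with the length of *continuous* secondary structure,
so the TDS of the amide I′ mode increases with helix length regardless of
solvation.

Because linear IR signals scale as |μ|² and 2D IR signals as |μ|⁴, the
ratio of the 2D diagonal to the linear OD isolates |μ|². With an
N-methylacetamide (NMA) calibrant — a single uncoupled amide I′ oscillator
with |μ|² = 0.12 D² — the TDS spectrum is

```
d(ω) = |ΔOD_s(ω,ω)| / OD_s(ω)
     × OD_c(ω_max) / |ΔOD_c(ω_max,ω_max)|
     × I_pump(ω_max) / I_pump(ω)
     × |μ_cal|²
```

where ΔOD(ω,ω) is the diagonal slice of the 2D spectrum, OD the
baseline-corrected linear optical density, and I_pump the pump-pulse
envelope. The double ratio cancels concentration, path length and pulse
geometry. The linear OD is baseline-corrected with airPLS (adaptive
iteratively reweighted penalized least squares, a Whittaker smoother with
residual-driven weights).

Calibrating d against model [EAAAK]ₙ peptides whose helical residue counts
come from circular dichroism (mean residue ellipticity at 222 nm, Eqs.
`[θ] = θ/(l·C·n)`, `%helicity = [θ]₂₂₂/[θ]_H`,
`[θ]_H = −40000(1 − x/n) + 100·T`) gives a linear TDS-vs-length law whose
inversion predicts the longest helix of an unknown protein. Because
delocalization cannot cross breaks in structure, the apparent TDS of a
multi-helix protein reports its *longest* helix, not an average.

The package implements, with tests at every stage:

- `spectra_io`: plain-text 1D/2D spectral dialects, OD from transmission;
- `baseline`: Whittaker smoothing and airPLS (`whittaker_smooth`,
  `airpls_baseline`, `correct_baseline`);
- `tds_core`: `diagonal_slice`, `calibrant_record`, `tds_spectrum`,
  `peak_tds`, `compute_tds`;
- `cd_helicity`: `mean_residue_ellipticity`, `theoretical_max_mre`,
  `percent_helicity`, `helical_residues`, `helicity_from_cd`;
- `helix_calibration`: `fit_calibration`, `predict_helix_length`,
  `predict_tds`, `frequency_trend`, with the built-in
  `ek_calibration_points()` table;
- `synthetic_data`: scene-based generators (`gen_linear_od`, `gen_pump`,
  `gen_2d_from_truth`, `gen_cd`, `random_scene`) with known ground truth.

## Worked example

```r
library(tdsir)

cal <- fit_calibration(ek_calibration_points())
cal
#> <helix_calibration TDS = 0.122 + 0.006669 * residues (D^2); r^2 = 0.981, n = 4>

predict_helix_length(0.21, cal, tds_sd = 0.006)   # lysozyme's measured TDS
#> <helix_prediction 13.2 +/- 1.2 residues from TDS 0.21 D^2>
predict_helix_length(0.30, cal, tds_sd = 0.007)   # myoglobin
#> <helix_prediction 26.7 +/- 2.1 residues from TDS 0.3 D^2 [extrapolated]>
```

13.2 and 26.7 residues match the longest helices of lysozyme and myoglobin
from their crystal structures; the `extrapolated` flag marks predictions
beyond the 20.2-residue calibration maximum.

A full synthetic measurement (generator → pipeline → prediction):

```r
pump    <- gen_pump(scene_spec(axis = c(1540, 1750, 1), seed = 1))
nma     <- calibrant_scene()                    # 0.12 D^2 single-amide band
od_cal  <- gen_linear_od(nma)
g2d_cal <- gen_2d_from_truth(nma, pump = pump, cal = 0.05)

sc <- scene_spec(bands = list(band_spec(1640, 22, 4, tds = 0.24)),
                 baseline_poly = c(0.06, -0.02), seed = 7)
d  <- compute_tds(gen_2d_from_truth(sc, pump = pump,
                                    cal = calibrant_record(g2d_cal, od_cal)),
                  gen_linear_od(sc), g2d_cal, od_cal, pump)
peak_tds(d, c(1630, 1650), assignment = "alpha-helix")
#> <tds_peak (alpha-helix) 0.2411 D^2 at 1630 cm-1, window [1630, 1650]>
```

The recovered 0.241 D² sits within 1% of the scene's 0.24 D² ground truth
after airPLS removal of the injected baseline. CD helicity works the same
way:

```r
meta <- cd_sample_meta(path_length = 0.1, concentration = 1e-3, n_residues = 23)
helicity_from_cd(gen_cd(0.88, meta), meta)
#> <helicity_result 88.0% helical (20.2 residues); [theta]222=-29526, [theta]H=-33552 deg cm^2/dmol>
```

A thin CLI over the same functions is installed at
`system.file("cli", "tds.R", package = "tdsir")` with subcommands
`compute`, `helicity`, `calibrate` and `predict-helix`.

## Limitations

- The TDS→length inversion applies to α-helices only; for β-sheets the
  relation between TDS and strand count is confounded by twist and
  rigidity, so the package reports β-sheet TDS values without a structural
  inversion.
- Synthetic spectra are line-shape emulations, not response-function
  simulations; see the methods vignette for what recovery tests do and do
  not demonstrate about experimental data.
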