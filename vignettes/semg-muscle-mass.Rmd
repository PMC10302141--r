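---
title: "Methods: sEMG amplitude features and muscle-mass estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEMG amplitude features and muscle-mass estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgmass)
```

# The measurement model

`semgmass` analyses isometric maximal voluntary contractions (MVC) of four
maneuvers — elbow flexion and extension, knee flexion and extension
(EF/EE/KF/KE) — recorded with a fixed electrode montage on the dominant limb:
three electrodes over the biceps brachii and two over the triceps on the
upper arm; three over the rectus femoris and three over the biceps femoris on
the thigh. During each maneuver one muscle group acts as agonist and the
opposing group as antagonist; `study_montage()` encodes the role assignment.

Each electrode trace is processed in the protocol's order: a 100–500 Hz
band-pass, full-wave rectification, then the RMS amplitude over an analysis
window. Per maneuver, the agonist electrode set is summarised by its mean
(*MeanRMS*, mV) and maximum (*MaxRMS*, mV), and *RatioRMS* divides MeanRMS by
the mean antagonist RMS recorded in the same maneuver — a dimensionless
co-contraction-style ratio that partially cancels subject-level scaling
factors (skin impedance, subcutaneous fat). *MVCstrength* (kg) is the
maximum force over three 3-s trials, earliest trial on ties. Which trial's
RMS is reported is not fixed by the protocol; the package takes the features
from the maximal-force trial, consistent with the MVC definition, and logs
the choice per subject (`source_trial_index`).

The statistical layer mirrors the study design: Pearson correlations paired
within maneuver and body segment (`correlation_table()`), stepwise ordinary
least squares for ASM on age, sex, height, weight and the twelve RMS
features (`stepwise_ols()`), VIF and Durbin–Watson collinearity/serial
diagnostics, a seeded 137/75 development/validation split, and
cross-validation by Pearson r and paired t-test. The published
fixed-coefficient equation is a separate, exactly reproducible calculator
(`predict_asm()`), with ASM/height² screening cutoffs of 7.0 (men) and
5.7 kg/m² (women); the inequality is taken as strict, a choice the source
leaves open.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| band edges | 100, 500 | Hz | the recording protocol's stated band |
| filter order | 4 | – | Butterworth section order; steep enough for 40 dB/octave stop-band after the double pass |
| apply mode | zero-phase | – | forward–backward pass avoids group-delay bias in 3-s windows |
| analysis window | 0.25 s per edge | s | excludes the force ramp and filter transients; no window is prescribed by the protocol |
| sampling rate (synthetic) | 4096 | Hz | Nyquist-sufficient for the 500 Hz band edge at desk scale; the original hardware rate (48 kHz) is configurable |
| trial duration | 3 | s | protocol value |
| stepwise thresholds | 0.05 / 0.10 | – | classic SPSS entry/removal defaults; the source names the software but not the thresholds |
| split sizes | 137 / 75 | subjects | the study's exact group sizes (its "30%" remark is inconsistent with 75/212 and is ignored) |
| sex coding | 1 = female | – | matches the published equation's indicator |

Durbin–Watson on a cross-sectional cohort depends on row order; the package
computes it in stored row order, which the pipeline keeps stable, and treats
it as a bookkeeping diagnostic rather than a time-series test.

# The synthetic cohort generator

No subject-level data are deposited, so every downstream stage is exercised
against a calibrated synthetic cohort.

**Correlation target.** The published tables pin down 72 pairwise Pearson
coefficients among MVC strength, the twelve RMS features, segmental lean and
fat masses, muscle thicknesses and ASM. `correlation_target()` embeds them
in the full 30-variable matrix; unspecified cells default to the
anchor-product rule `r_ij = r_iA * r_jA` through ASM, encoding "everything
co-varies through overall muscularity" (a one-factor structure that is
automatically near-positive-semidefinite). A zero fill is retained as an
option. Two groups of cells are package assumptions rather than published
values: anchor correlations with ASM for variables whose ASM correlation is
unpublished (chosen from standard body-composition physiology, e.g. height
0.85, latent female −0.80, segmental lean masses 0.93–0.95, strength
0.60–0.75), and within-maneuver feature correlations (MeanRMS–MaxRMS 0.95,
MeanRMS/MaxRMS–RatioRMS 0.50/0.45) — the mean and max summarise the same
electrodes and are necessarily tightly coupled; leaving them near zero would
make sampled (MeanRMS, MaxRMS) pairs frequently infeasible as electrode
sets. The assembled matrix is projected to the nearest valid correlation
matrix by iterated eigenvalue clipping with diagonal rescaling
(tolerance 1e-10); the provenance of every cell (`printed`, `filled`,
`repaired`) and the largest post-repair change on a published cell are
reported. Full Higham alternating projections were judged unnecessary at
this size; the test suite cross-checks the repair against `Matrix::nearPD`.

**Marginals.** The published summary gives means and SDs only, so marginal
shapes are a design choice. Each continuous variable uses a moment-matched
truncated normal: the parent normal's parameters are solved (1-d root find
on the standardized truncation point) so that after truncation at the
physical floor (0 for masses, amplitudes, forces and thicknesses; 18 years
for age) the marginal mean and SD equal the published values exactly, and
latent Gaussian coordinates are mapped through the truncated quantile
function. An earlier design that rejected and redrew whole rows below the
floors was abandoned: rejection conditions the shared latent factor upward
and biases *every* correlated marginal, measurably beyond the generator's
2% calibration envelope for the smallest RMS marginals (whose floors sit
only ~2.3 SD below the mean). Sex is a thresholded latent coordinate (cut
at the quantile matching the target female fraction), so sex–variable
correlations are representable on the latent scale; per-sex conditional
means are not separately calibrated because only pooled marginals are
published. BMI is always recomputed from height and weight.

Two reported values are internally inconsistent and handled explicitly. The
total-cohort RatioRMS(EE) mean is printed as 2.44 while both subgroup means
are 1.44/1.43; the package uses 1.44 and treats the total as a typo. The
MaxRMS(EE) mean (0.31 mV) is printed *below* the MeanRMS(EE) mean (0.73 mV),
impossible for a maximum and mean over the same electrodes; the tabular
generator emits the published marginals unchanged (so calibration against
the summary table remains meaningful), and the inconsistency is resolved
only at signal-rendering time, where the max target is clipped up to the
mean with a warning. Round-trip checks therefore compare recovered MaxRMS
against `max(mean, max)`.

Dominant-arm/leg segmental lean and fat mass marginals are not published at
all; the package assumes arm lean 2.4 (0.7), leg lean 7.1 (1.7), arm fat
1.2 (0.5) and leg fat 3.0 (1.0) kg — values consistent with the cohort's
ASM mean of 18.95 kg (ASM ≈ 2 × (arm + leg lean)) and typical for a healthy
40–80-year cohort of this build.

**Signal rendering.** `render_trial_signals()` inverts a subject's tabular
features into raw trials. Per-electrode RMS targets come from
`derive_electrode_rms()`: for two agonist electrodes the solution of the
mean/max system is unique; for three, the two non-maximal electrodes share
the remainder in equal halves with up to 5% multiplicative jitter, capped so
neither exceeds the maximum. Antagonist electrodes each receive
MeanRMS/RatioRMS. Traces are Gaussian noise band-limited to an interior
180–420 Hz slice of the recording band and rescaled so the windowed RMS
meets the target exactly; the interior band keeps the 100–500 Hz recording
filter transparent on reprocessing (noise shaped by the recording filter
itself loses about 5% RMS to the filter's own skirts on a second pass —
the squared-magnitude response integrates below unity — while the interior
band loses under 1%). A 0.25-s linear ramp pads each end of the 3-s
contraction and is excluded from the analysis window. One trial per
maneuver, chosen from the seeded stream, carries the subject's MVC force;
the others are submaximal copies with force and amplitude scaled by a
factor in [0.85, 0.98].

The generator emulates the *second-order structure* of a study cohort —
marginal moments, floors, pairwise correlations — and the amplitude
structure of band-limited sEMG. It does not emulate motor-unit physiology,
signal nonstationarity within a contraction, fatigue, tremor,
electrode-shift artifacts, per-sex or per-age conditional structure, or
non-Gaussian dependence (tail dependence, nonlinear relations). Passing
calibration and round-trip tests therefore demonstrates the pipeline's
correctness and internal consistency, not that real recordings would yield
the published coefficients.

# Numerical choices

- **Zero-phase filtering** is realized as the symmetrized forward–backward
  pass `(filtfilt(x) + rev(filtfilt(rev(x)))) / 2`. The underlying
  `signal::filtfilt` pads only the trailing end, leaving
  direction-dependent edge transients; symmetrization makes filtering
  commute with time reversal to machine precision while leaving interior
  samples essentially unchanged. Traces shorter than three high-pass
  impulse spans are rejected rather than silently filtered.
- **Rectification** is kept as an explicit stage for fidelity to the
  recording protocol although it cannot change an RMS (`|x|² = x²`); the
  identity is verified as a property test.
- **PSD repair** clips eigenvalues at zero and rescales the diagonal,
  iterating to a 1e-10 fixed point; valid matrices pass through unchanged
  and the iteration is idempotent to 1e-8.
- **Truncated-normal solving** uses log-scale hazard evaluation, stable for
  truncation points as far as 40 SD into the tail.
- **Stepwise selection** stops on cycles (visited-model set) and on
  numerically perfect fits, where partial-F p-values are meaningless; a
  condition number above 1e10 in the final fit is an error, and perfectly
  collinear VIF inputs are reported as `Inf` with a flag rather than an
  error. Ties in MVC forces resolve to the earliest trial.
- **Degenerate validation inputs** (all prediction errors identical, e.g. a
  noiseless round trip) bypass the paired t-test: p = 1 for zero mean
  difference, p = 0 otherwise.
- The pipeline configuration key for cohort size is `n_subjects` because a
  bare `n` is a boolean literal in YAML 1.1.

# Problem sizes in the test suite

Calibration checks sample 50,000 subjects (Monte Carlo SE on a correlation
about 0.004, comfortably inside the 0.03 calibration envelope); rendering
round trips cover 50 subjects across all four maneuvers at 4096 Hz;
stepwise recovery runs 100 seeds at n = 1000 with 8 candidates, and the
published variable pool is exercised at n = 10,000 against a cohort whose
ASM is generated by the published equation plus Gaussian noise with the
published residual SD (1.167 kg). These sizes were chosen so each check's
sampling error is small relative to the tolerance it enforces.

# Known limitations

- The copula's one-factor fill understates the joint dependence of ASM on
  its covariates relative to the real cohort, so synthetic in-sample R² and
  cross-validation r are systematically below the published ones; the
  package's acceptance checks are therefore pinned to the published
  pairwise quantities and the equation's algebra, not to the headline fit
  statistics.
- Stepwise selection on 212-subject draws is unstable by nature: correlated
  maneuver features substitute for one another across seeds. Height, weight
  and sex are retained throughout; the specific RMS features vary.
- EDF support covers the common continuous-recording subset (16-bit, equal
  per-channel rates, mV/µV physical dimensions) — sufficient for
  round-tripping this package's signals, not a general EDF(+) reader.
- The published equation is validated only over the study's covariate
  ranges; predictions outside them are produced (not floored) but should
  not be interpreted.
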