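---
title: "Methods: quantitative SPECT dosimetry for radioiodine therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative SPECT dosimetry for radioiodine therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridose)
```

## The problem

Differentiated thyroid cancer is commonly treated after thyroidectomy with
fixed administered activities of Na[131I]I (radioiodine), typically 1.1 or
3.7 GBq. The absorbed doses that such fixed administrations deliver to
normal organs — salivary glands, lungs, kidneys, the bone marrow — vary
widely between patients, and measuring them requires quantitative SPECT
imaging, kinetic modelling of iodine washout, and a dose calculation.
`ridose` implements that chain as a reusable, fully testable pipeline:

1. **Calibration** — system-volume sensitivity (cps/MBq) and
   recovery-coefficient curves for partial-volume correction;
2. **Quantification** — counts-to-activity conversion, fixed-threshold VOI
   segmentation, voxel-summation time-activity extraction;
3. **Kinetics** — mono-exponential organ fits, single-time-point
   extrapolation with fixed effective half-lives, constrained bi-exponential
   whole-body retention fits; all yield time-integrated activity (TIA,
   MBq h) and TIA coefficients (TIAC = TIA/A0, hours);
4. **Voxel dosimetry** — dose-kernel convolution of activity maps
   (charged-particle/local-deposition model), mass-averaged VOI dose rates
   and their time integral;
5. **Whole-body dosimetry** — MIRD formalism with a mass-adjusted
   whole-body S-factor;
6. **Cohort reporting** — median (range) of doses per administered activity
   by organ and centre, with exact Mann-Whitney group comparisons.

Because clinical image sets of this kind are not publicly deposited, the
package ships a synthetic-data module that generates every input the
pipeline needs — digital phantoms, noisy blurred acquisitions, retention
series, calibration sets — with machine-readable ground truth, so the whole
chain can be validated end to end.

## Models and assumptions

### Kinetics

Organ activity is modelled as instantaneous uptake at administration
followed by mono-exponential washout, \(A(t) = A_0 e^{-\lambda t}\) with
\(\lambda = \ln 2 / T_\mathrm{eff}\). The time-integrated activity is the
closed-form integral from 0 to infinity, \( \tilde A = A_0/\lambda \).
Instantaneous uptake is an assumption, not an observation: clinical data
begin at the first scan (6 h at the earliest), and the single-time-point
closed form presupposes it. Series that do not decrease over a span of more
than 24 h are flagged `uptake_suspected` rather than rejected, so the audit
trail survives.

Effective half-lives cannot exceed the physical half-life of I-131
(8.02 d = 192.5 h, a configurable constant, `i131_half_life_h()`). Noisy
data can nevertheless produce slower fits; these are clamped to the
physical bound and flagged `half_life_clamped`, keeping the record
auditable instead of failing the patient.

For exactly two points the fit is the exact closed form. For more points, a
log-linear least-squares fit weighted by activity (which de-emphasises the
noisy late tail on the log scale) initialises an unweighted nonlinear
least-squares refinement on the linear scale (`minpack.lm`).

**Single-time-point dosimetry.** When only one scan exists, an assumed
effective half-life drives the extrapolation:
\(\tilde A = A(t_1)\, e^{\lambda t_1}/\lambda\). The shipped defaults
(`half_life_defaults()`) are 68 h for the neck uptake region and 9.3/8.6 h
for parotid/submandibular glands, literature-derived values used in
multi-centre practice; for other organs the patient's fitted whole-body
half-life is supplied explicitly. Note a subtlety the tests document: with
\(A(t_1)\) held fixed, \(\tilde A\) increases with the assumed half-life
only while \(t_1 < T_\mathrm{eff}/\ln 2\); for measurements late relative
to the assumed half-life, back-extrapolation dominates and the ordering
reverses.

**Whole-body retention.** Retention is fitted with 1 or 2 exponentials
under hard constraints: amplitudes non-negative and summing to the
administered activity (retention = 100% at t = 0), decay constants between
physical decay and a 30-minute half-life. The optimiser is a deterministic
multi-start (half-life pairs from {2, 8, 24, 96} h) of box-constrained
L-BFGS-B followed by bounded Levenberg-Marquardt polish; determinism was a
design requirement (a spreadsheet solver, whose algorithm is unspecified,
would not be testable). The 2-component fit falls back to 1 component when
fewer than 4 points are available or when the second component does not
reduce the residual sum of squares by at least 5% — including the
degenerate case where the 1-component fit is already essentially exact.
How many components the original analyses used is not documented anywhere
we could rely on; 2-with-fallback is this package's decision, as is
anchoring to A0 rather than to the first measurement.

### Calibration and partial-volume correction

The calibration factor is count rate over known activity. Recovery
coefficients RC = measured/true from a sphere series are clipped to (0, 1]
and repaired to be non-decreasing in volume by least-squares
pool-adjacent-violators (`stats::isoreg`) — partial-volume loss can only
worsen as objects shrink, so monotonicity is physics, not preference.
Between nodes RC is interpolated linearly in log10(volume), the
conventional axis for recovery curves, and clamped to the end nodes outside
their range. Whether recovery correction is applied to organ activities or
only characterised at set-up differs between sites; `extract_time_activity`
takes the curve as an optional argument, so both pathways are supported
without asserting either as canonical.

### Segmentation

Where anatomical imaging is unavailable, organs are segmented on the
activity image by a fixed 35% threshold of the maximum inside a
user-supplied search region, followed by largest-6-connected-component
selection (ties broken by total intensity). The search region makes the
threshold local — thresholding a whole-body image at 35% of its global
maximum would swallow the neck remnant and nothing else. The threshold
maximum is per-time-point; whether a series-wide maximum would be
preferable is a protocol choice surfaced in the interface, not hard-coded.
CT-derived segmentation is represented by accepting externally supplied
masks on the same grid; no registration is in scope (synthetic series are
generated aligned).

### Voxel dosimetry

The dose engine is voxel S-value kernel convolution restricted to charged
particles. A kernel is an odd-sided array of S-values (Gy per MBq h) with a
declared voxel spacing and an energy constant
\(\Delta\) (Gy g per MBq h); construction enforces *energy closure* —
S-values times the reference voxel mass must sum to \(\Delta\) within
1e-6 — so a kernel can redistribute exactly the energy emitted, no more.
The default engine is the 1x1x1 local-deposition kernel
(\(S_{000} = \Delta / m_\mathrm{voxel}\)), appropriate for organs large
relative to the I-131 beta range (~1 mm in soft tissue); multi-voxel
kernels are read from CSV and never silently resampled (spacing mismatch
beyond 1% is an error, a known failure mode of S-value tables).
\(\Delta\) derives from a mean charged-particle energy per decay of
0.192 MeV, shipped as a configuration default (`energy_delta()`), giving
0.1107 Gy/h for 1 MBq in a 1 g voxel.

Heterogeneity is handled to first order by scaling each target voxel's
dose rate by reference/local density. This preserves energy exactly
(conservation holds for any density map) and reduces to exact behaviour in
uniform media, where interior voxels of an extended source reach
charged-particle equilibrium: convolution equals local deposition, a
property the tests check to 1e-3.

Organ dose is the time integral of the mass-averaged VOI dose rate
(total energy deposition rate over VOI mass), fitted mono-exponentially
exactly as activity kinetics are.

### Whole-body MIRD dose

\(D_\mathrm{WB} = \tilde A \times S_{\mathrm{WB}\leftarrow\mathrm{WB}}\)
with the mass-adjusted S-factor
\(S = 1.34\times 10^{-4}\, m_p^{-0.921}\) Gy MBq\(^{-1}\) h\(^{-1}\),
applied exactly as printed, with no photon/electron split. The whole-body
dose is frequently used as a surrogate for the bone-marrow dose; that
relationship is documentation, not computation. Dose per administered
activity \(d = D/A_0 \times 1000\) (mGy/MBq) is invariant under joint
rescaling of \(A_0\) and \(\tilde A\) — the formal counterpart of the
empirical observation that whole-body doses scale with administered
activity.

### Cohort statistics

Group summaries are median (midpoint of the central pair for even n) and
range, excluding missing organs — an organ outside a patient's field of
view is absent, never zero. Group comparisons use the Mann-Whitney U test
with midranks; for `min(n) <= 8` (and at most 1e5 arrangements) the
two-sided p is exact by full enumeration,
\(p = \min(1,\, 2\min(P(U\le u), P(U\ge u)))\), otherwise a normal
approximation with tie-corrected variance and continuity correction is
used. The exact threshold and correction are this package's choices for
small-cohort fidelity; base R's `wilcox.test` cannot compute exact p-values
under ties, which is why the exact branch is implemented here (the
approximation branch is cross-checked against `wilcox.test` in the tests).

## The synthetic-data generator

`make_phantom` voxelises geometric primitives (sphere/ellipsoid/box; a
voxel belongs to a primitive when its centre is inside) into density maps,
disjoint VOI masks and a ground-truth table (voxelized volume, mass,
activity, TIA, local-deposition dose). `make_timeseries` decays each organ
mono-exponentially, applies an isotropic Gaussian blur (the standard
first-order model of SPECT resolution and the minimal mechanism that makes
recovery coefficients nontrivial), scales by the system sensitivity and
optionally adds Poisson counting noise, seeded and bit-reproducible.
`make_retention_series` samples a 1- or 2-exponential retention model
normalised to A0 with multiplicative Gaussian noise;
`make_calibration_set` produces the sensitivity acquisition and blurred
sphere series. Centre-specific schedules are emulated simply by the time
vectors supplied (e.g. external counting to 167 h versus 44 h).

Default study conditions used throughout the tests and the acceptance
script: organ washout half-lives of 68 h (neck), 9.3 h (salivary), 14-16 h
(lungs, liver, spleen); bi-exponential whole-body retention with a
0.4-0.7 fast fraction at 4-10 h and a slow component at 18-30 h (median
TIAC near 18 h, the range reported for such cohorts); 5% relative
measurement noise on retention; imaging at 24/48/96 h; patient masses
around 75 +/- 12 kg; 3.7 GBq administrations with a 1.1 GBq subgroup at one
centre and THW stimulation in a minority at two centres. Problem sizes are
deliberately desk-scale — 24x24x48 phantom grids at 4 mm, 20-40 patient
cohorts, 100-replicate noise studies — chosen so the full validation chain
runs in seconds while still exercising every code path at realistic
parameter values.

What the generator does *not* emulate — and hence what green tests do not
show about clinical data: no projection/reconstruction (no OSEM artefacts,
no scatter or attenuation residuals), no registration error (series are
generated aligned), no uptake phase (instantaneous uptake matches the
fitting assumption by construction, so parameter-recovery tests cannot
detect uptake-model misfit), no anthropomorphic anatomy, and no dead time.
The generator validates the mathematics of the pipeline, not the physics of
a camera.

## Numerical choices

- **Convolution** is shift-and-accumulate over non-zero kernel offsets with
  zero padding, exact to machine precision against a brute-force
  superposition oracle (tested at 1e-10 on 11^3 grids; in practice
  agreement is exact).
- **Blur** is separable with 1D kernels truncated at +-4 sigma and
  renormalised to sum to 1, so grid totals are conserved to 1e-6 for
  objects clear of the boundary.
- **Voxelization** uses the voxel-centre rule, deterministic and testable;
  a sphere spanning >= 8 voxels per axis voxelises within ~5% of the
  analytic volume when not pathologically placed (a sphere centred exactly
  on a lattice corner with the inclusive boundary rule can overcount
  slightly beyond that).
- **Retention optimisation** uses L-BFGS-B with `factr = 10` and
  Levenberg-Marquardt polish at `ftol = ptol = 1e-15`; noise-free
  bi-exponential parameters are recovered to 0.1%.
- **TIA** is always the closed-form sum \(\sum a_i/\lambda_i\); adaptive
  quadrature of the fitted model (plus analytic tail) agrees to 1e-6 and
  serves as the independent oracle in the tests.
- **Ties and seeds**: every stochastic generator takes an explicit integer
  seed and restores the caller's RNG state; component ordering (faster
  first), connected-component tie-breaks (total intensity) and the exact
  Mann-Whitney enumeration are all deterministic.

## Known limitations

- Photon cross-dose between organs is out of scope; the kernel pathway is
  charged-particle only, so organ doses here underestimate total absorbed
  dose where photon self- and cross-irradiation matter.
- Single-time-point dosimetry inherits the full uncertainty of the assumed
  half-life; for short-lived uptake (salivary glands) a late scan carries
  almost no information, and the package will faithfully report the small
  extrapolated dose rather than warn it is unreliable.
- Short retention-counting windows (measurements stopping near 44 h)
  identify the slow component poorly; with noise, individual whole-body
  TIACs can be biased high even though cohort medians remain stable. The
  fits are flagged when they clamp, but a well-identified fit on a short
  window can still be imprecise.
- No registration, attenuation or scatter correction: clinical use assumes
  upstream reconstruction and alignment have produced quantitative,
  co-registered activity maps.
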