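---
title: "Methods: photoreceptor-selective retinotopic mapping with retinomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photoreceptor-selective retinotopic mapping with retinomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retinomap)
```

This vignette is the package's account of its models and the design
decisions behind them: what is computed, under which assumptions, which
parameters matter, and what the synthetic study conditions do and do not
emulate.

## 1. Silent substitution

A three-primary display can silence at most two photoreceptor classes.
Writing `M` for the 4×3 excitation matrix (rows L, M, S, rod; columns R, G,
B) built by Riemann-summing each primary's spectral power distribution
against each receptor sensitivity on a common 390–780 nm / 1 nm grid
(`build_excitation_matrix()`), receptor excitation is linear in the
*linearized* drive. Gamma is an explicit per-channel exponent so that
calibration errors of the kind that actually limit rod silencing (a
mis-estimated gamma) can be injected and measured with `validate_pair()`.

- **Cone-isolating pairs** modulate only R and G along the rod-null
  direction `(M[rod,G], −M[rod,R])` of the linearized red–green plane.
  Keeping blue fixed concentrates the modulation at long wavelengths where
  rods are least sensitive, so residual rod contrast from measurement error
  stays small. The step along the null direction is solved with
  `uniroot()` (tolerance 1e-14) so that the *mean of the L- and M-cone
  Michelson contrasts* equals the request; the rod excitation difference
  cancels exactly by construction.
- **Rod-isolating pairs** modulate along the cross product of the L and M
  rows (the null space of both cone constraints). The S-cone contrast is
  reported but necessarily uncontrolled.
- Contrasts are Michelson, `|e_t − e_b| / (e_t + e_b)`, stored signed
  (positive = increment). Because the denominator moves with the step,
  drive deltas are proportional to the requested contrast only to first
  order; the package solves the exact nonlinear equation rather than the
  linear approximation.
- The background default is mid-grey drive (0.5, 0.5, 0.5); one-sided
  modulation from it is the default and a `bidirectional` flag produces a
  symmetric increment/decrement pair.

No tabulated standard-observer fundamentals are bundled; the shipped
fixtures are generated from the package's log-wavelength Gaussian
photopigment template (`photopigment_template()`) at canonical peaks
(L 566, M 541, S 441, rod 507 nm) and are labelled synthetic. They
reproduce the overlap structure that makes silent substitution nontrivial;
they are not psychophysical measurements, and absolute contrast values on a
real display will differ. The same applies to `synthetic_display_model()`.

## 2. The mapping protocol

One run is 348 frames at TR = 1 s: 20-s fixation baselines at the start,
mid-point and end, and 288 s of simultaneous stimulation by an
expanding/contracting ring (6 cycles of 48 s, logarithmic eccentricity
scaling) and a rotating 20°-wide wedge (8 cycles of 36 s, 10°/frame),
within a ±8.6° field. Choices the protocol description leaves open, fixed
here: minimum ring-centre eccentricity 0.5°; ring width 0.5 × centre
eccentricity (a log-scaled annulus whose outer edge reaches 8.6° at the end
of an expanding cycle); the mid-run baseline splits stimulation
symmetrically (144 s + 144 s); wedge masks are half-open in angle so the
wrap is never double-counted; the aperture grid defaults to 4 px/deg.
Only apertures are modelled — the checkerboard carrier does not enter the
pRF prediction.

## 3. pRF model and two-stage fit

A vertex's neural drive at frame *t* is the overlap of an isotropic
bivariate Gaussian (centre x, y; SD σ) with the binary aperture, normalized
by the Gaussian's total mass on the grid, then convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6, 32-s support,
unit-sum; the HRF is not part of the original analysis description, so the
canonical parameterization is used and amplitude is left free).

Fitting is two-stage:

1. **Coarse:** the data are smoothed along the cortical surface (Gaussian
   kernel on geodesic distances, FWHM 5 mm, truncated at 3 SD) and an
   exhaustive grid search maximizes the Pearson correlation with
   precomputed grid predictions. The default grid is 12 log-spaced
   eccentricities to 9° × 24 angles plus the origin, and 8 log-spaced σ
   values 0.18–9° — slightly beyond the stimulated field because real fits
   pile up at edges. Ties break to the first grid index; zero-variance
   series are flagged unfit.
2. **Fine:** vertices whose coarse R² exceeds 0.05 are refined by
   Nelder–Mead, minimizing the residual sum of squares over
   (x, y, σ, amplitude, baseline) against the *unsmoothed* series
   (relative tolerance 1e-7). The two linear parameters are profiled out —
   each candidate shape gets its exact least-squares amplitude and
   baseline — so the simplex searches only (x, y, log σ) of the same
   objective; the log-σ transform guarantees positive sizes. If the
   simplex exhausts its iteration budget it restarts once with a fresh
   simplex (high-eccentricity fits occasionally stall otherwise); if it
   fails to improve on the start, the start is returned flagged.
   Vertices below the
   fine threshold carry their coarse parameters and coarse R² forward —
   this matters for realism: weakly correlated noise vertices survive the
   map threshold exactly as they do in grid-search toolboxes, which is why
   untreated (silent) cone maps retain a substantial noise-driven fraction
   at R² > 0.03 rather than being empty.

Fitted x, y and σ are then surface-smoothed (FWHM 3 mm, across fitted
vertices only), converted to eccentricity and polar angle (0° = right
horizontal meridian, anticlockwise positive, range (−180, 180]), and
thresholded at R² > 0.03 (p = 0.0012 at n = 348; the stringent alternative
0.05 ↔ p = 3e-05 is a config switch). R² is the squared Pearson correlation
between model and data in both stages. The two runs per condition are
averaged sample-wise before fitting, keeping n = 348.

## 4. Rod–cone correspondence statistics

From vertices surviving the threshold in *both* maps (the stricter pairing
choice), the package computes:

- **Orthogonal regression** (total least squares via the first principal
  axis): correspondence predicts slope 1, intercept 0; unlike ordinary
  least squares the slope is not attenuated by noise in the rod angles.
- **Identity-model Akaike weight.** Three models of the paired angles:
  identity (φ = θ), a horizontal level (φ = constant) and a vertical level
  (θ = constant), the levels representing unstructured data in the cone or
  rod map. Angles are treated *linearly* by default — unwrapped residuals
  and arithmetic-mean levels — which is what gives the comparison its
  power: when the cone map is noise, the identity model's residual
  variance is the sum of both maps' angular variances while each level
  model pays only one, a systematic ~2× penalty that drives the identity
  weight to zero on unstructured maps of any size. (Reported intercepts
  far outside (−180, 180]-wrapped reach, e.g. strongly negative slopes
  and intercepts on unstructured maps, are a signature of this linear
  treatment.) Wrapping residuals to (−180, 180] respects the angular
  topology but caps the identity residuals of two *independent* maps at
  the same uniform plateau the level models sit on, so the three models
  become statistically indistinguishable on null data and the weight is
  decided by parsimony and sampling noise; the wrapped variant is
  provided as an option, with the level models then fitted by exactly
  minimizing the wrapped RSS (piecewise quadratic in the level; AIC
  compares maximized likelihoods, so centring the level models at the
  circular mean — also available — understates them on multimodal
  samples). `AIC = n log(RSS/n) + 2k` with k = 1 for identity (noise
  variance only) and k = 2 for the level models; an ε floor of 1e-12 on
  RSS guards exact fits. The reported weight is the identity model's
  relative likelihood.
- **Fisher–Lee circular correlation** with a seeded permutation test
  (`p = (1 + #{|CC_perm| ≥ |CC_obs|}) / (n_perm + 1)`), rotation-invariant
  by construction.
- **Normative envelope:** the 95% (slope, intercept) coverage ellipse from
  the control sample mean/covariance at the χ²(2) radius, plus the
  empirical 95% CC range; `classify_against_envelope()` reports
  inside/outside per index. The same machinery runs on x, y and
  eccentricity estimates through `linear_correspondence()` (unwrapped
  residuals, Pearson correlation).

## 5. Coverage and size–eccentricity profiles

Coverage renders each retained pRF as a *peak-normalized* Gaussian and
takes the pointwise maximum (0.1° grid). Peak normalization is deliberate:
a single large foveal pRF produces high coverage over a broad area, which
is the intended reading of the statistic (and its acknowledged caveat).
Size profiles bin pRFs into half-open 1° eccentricity bins over 0.5–8.5°
and take the median σ per bin; a bin is excluded when it holds fewer than
10% of the pRFs in the matching bin of a reference condition (in the
synthetic pipeline the rod map serves as the reference, since no separate
non-selective condition is simulated). Group envelopes give the t-based
95% CI and the 2.5–97.5 percentile range per bin, omitting profiles only
from bins where they are missing.

## 6. Staircase psychophysics

Both tasks use a 1-up/1-down rule over 21 contrast steps (step 1 = highest
contrast), converging on 50% correct: correct responses step toward lower
contrast, errors (and "nothing visible" reports, which are treated as
errors) step back. Stops: ≥ 14 reversals (square task) or ≥ 8 (ridge), or
more than 8 correct responses at the lowest contrast (ceiling). The
threshold estimator is the mean of the last 6 reversal levels (the
procedure description fixes only the rule and stop criteria); ceiling runs
report the lowest-contrast level. The default step-to-contrast ladder is
log-spaced over two decades from 0.52, near the mean-L/M gamut ceiling of
the synthetic display. Simulated observers are Weibull:
`P(c) = γ + (1 − γ)(1 − λ)(1 − exp(−(c/α)^β))` with guess rate 0.25 (4AFC)
or 0.5 (ridge) and lapse ≤ 0.1. The untreated-group interval is the
t-distribution 95% prediction interval `mean ± t · s · √(1 + 1/n)`;
thresholds strictly below it count as improved beyond the untreated range
(boundary values are within).

## 7. The synthetic study conditions

`make_ground_truth()` builds two rectangular lattice patches (left/right
hemisphere), each carrying a complex-log-style template: log eccentricity
along one axis (0.5–8.6°), polar angle along the other (each hemisphere
representing the contralateral hemifield), σ = 0.5° + 0.2°/deg × e — a
standard V1-like size–eccentricity relation — plus 0.1° positional jitter.

Two choices deserve emphasis:

- **Lattice spacing 3 mm.** A reduced-vertex sheet should *subsample* a
  cortex-sized surface, not shrink it. What controls the statistics of
  noise-driven maps is the number of independent smoothing patches
  (sheet area / smoothing kernel area), which in a real V1–V3 surface is
  in the hundreds. At 3 mm spacing a 220-vertex sheet spans roughly
  30 × 30 mm per hemisphere and preserves a realistic patch count under
  the 5-mm kernel; at 1-ish mm spacing the same vertex budget would
  collapse to a handful of independent patches and every map-level
  statistic would be dominated by a few noise clumps.
- **Noise AR(1) ρ = 0.3 in the pipeline conditions.** BOLD noise is
  temporally autocorrelated, and that autocorrelation is what lets a
  fraction of pure-noise vertices pass the (deliberately lenient)
  R² > 0.03 threshold, as observed in real untreated cone maps (~50%
  retention). With white noise the silent maps are nearly empty and the
  null experiment degenerates, so the full-pipeline study conditions use
  the AR(1) option; `simulate_bold()` itself defaults to white noise for
  component-level tests. tSNR is defined as signal peak amplitude / noise
  SD (default 50); silent maps are the same seeded noise stream without
  the signal, so conditions are paired by seed.

What the generator does **not** emulate: spatially correlated physiological
noise, cortical folding and variable vertex density, nystagmus (an optional
aperture-jitter transform is the hook for that confound, off by default),
the foveal rod scotoma, S-cone intrusion into rod maps, and any fitting-
software-specific foveal bias. Passing the synthetic separation experiment
therefore shows that the *pipeline* cannot conjure retinotopic structure
from stimulus-locked-signal-free data and reliably detects it when present
— it does not certify behaviour under every real-data pathology.

`null_structure_experiment()` packages the core robustness claim: across
many seeded datasets with responsive rod maps and silent cone maps, the
identity-model Akaike weight essentially never exceeds 0.5 (more noise does
not add more structure), while fully responsive pairs give weights ≈ 1 and
circular correlations ≈ 1.

## 8. Problem sizes and numerical choices

The shipped tests and the acceptance script run reduced problem sizes,
chosen as the smallest that leave the qualitative results stable: aperture
grids at 2 px/deg, a coarse grid of 8 eccentricities × 16 angles × 6 σ,
220-vertex sheets for the separation experiment (50 silent + 10 responsive
datasets), 200 vertices for parameter recovery, and simplex iteration caps
of 150–500 per start (with the single restart described above). Numerical
details: grid predictions are computed once per
design and shared; convolution is FFT-based; aperture masks are stored
sparse for the per-evaluation overlap product; correlation ties in the
coarse fit break to the first grid index; degenerate cases (zero-variance
series, all-equal angles, singular control covariance, empty pRF sets)
return flagged values or errors rather than numbers.

## 9. Known limitations

Calibration assumes spatially uniform display output and a scalar
attenuation per channel; S-cone silencing is impossible with three
primaries and is only reported, not controlled. The pRF model is isotropic
Gaussian — no surround suppression, no anisotropy. The AIC bookkeeping
treats paired vertices as independent observations, which they are not
under surface smoothing; the normative-envelope comparison inherits the
same caveat. These match the analysis being modelled rather than improve
on it.
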