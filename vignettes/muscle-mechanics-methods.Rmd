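---
title: "Methods: in situ muscle mechanics and morphometry with myomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in situ muscle mechanics and morphometry with myomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomech)
```

`myomech` turns raw in situ muscle recordings — tetanic length series,
high-frequency trains, repeated-contraction runs — and specimen/fiber
measurements into the standard contractile and morphometric phenotype
variables. This vignette documents the models, the estimators, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The length–force model

An isometric length series evokes one fused tetanus per muscle length,
preceded by two conditioning twitches. Three curves live in such a series:

- **Passive force** `P(L)`, measured as the mean force in the quiet window
  between the second twitch and the tetanus (`extract_passive_force()`,
  with a 50 ms settle margin after the twitch by default), is described by
  a second-order exponential. The printed form of this family is ambiguous
  between an offset exponential and an exponential of a quadratic, so both
  are implemented: the default `P(L) = exp(b0 + b1 L) + b2` keeps all
  three coefficients interpretable (rate, scale, resting offset) and is
  the common parameterization of passive muscle curves;
  `form = "exp-quadratic"` selects `exp(b0 + b1 L + b2 L^2)`.
- **Active force** `A(L) = T(L) − P(L)` uses the *measured* passive value
  at each length, not the fitted curve: the fitted passive curve describes
  the passive relation, but subtracting it would leak its model error into
  the active points. (`subtract = "fitted"` switches this.) Values near or
  below zero close to slack are retained; clipping would bias the slack
  estimate upward.
- The active relation is fitted with polynomials of order 2–5.

### Polynomial order selection

Nested fits are compared by the extra-sum-of-squares F-test,

$$F = \frac{(RSS_k - RSS_{k+1})/1}{RSS_{k+1}/(n - k - 2)},$$

which is the one statistically coherent reading of "comparing nested fits
by ANOVA". The selected order is the lowest $k$ whose step to $k+1$ is not
significant at $\alpha = 0.05$; if every step improves, order 5 is kept.
No multiplicity correction is applied over the (at most three) sequential
comparisons. Near-exact fits are detected with a tolerance *relative* to
the total sum of squares, which keeps the whole procedure invariant to
rescaling forces (a property the test suite asserts). With fewer than 7
points the search is capped at the highest estimable order, with a
warning; rank-deficient orders are skipped.

### Optimum and slack extraction

`L_mao` is the argmax of the selected polynomial restricted to the
measured length range, computed from the real roots of the derivative
polynomial compared against the endpoints (a dense 1 mm/1000 grid is the
fallback). An argmax at a range boundary is flagged: the true optimum may
lie outside the measured range. `L_mas` is the largest real root strictly
below `L_mao`; the search window extends below the lowest measured length
by at most 25% of the measured span, because uncontrolled polynomial
extrapolation manufactures spurious roots. Roots are isolated from the
polynomial's root set plus sign changes on a 1 µm grid and polished by
bisection to 1e-6 mm. When the fitted curve never crosses zero in the
window the result is an explicit "slack not bracketed" error carrying the
lowest evaluated force — a real outcome for noisy series whose ascending
limb is too shallow, and one the pipeline treats as an unanalyzable
dataset rather than a number.

`F_mao` is reported as the polynomial maximum; the largest *measured*
active force is reported alongside (`F_mao_measured`), since reported
optimum forces can follow either convention.

### Passive-fit numerics

`fit_passive()` uses Levenberg–Marquardt (`minpack.lm`) with a
deterministic multi-start on the rate coefficient: a log-linearized start
(regressing `log(P − offset)` on length) plus five fixed rates spanning
gentle to steep, keeping the lowest-RSS convergent fit (ftol/ptol 1e-10,
200 iterations). An all-zero passive series returns a degenerate,
flagged, offset-only fit predicting zero. When active decomposition uses
measured passive values, a passive fit that fails from every start
degrades to a warning — the descriptive curve is lost, the decomposition
is not.

## Trace dynamics

**MRFD.** The maximal rate of force development is the peak slope of the
baseline-corrected force rise during a high-frequency train, between the
train onset and the first plateau sample. The derivative estimator is a
local-polynomial (Savitzky–Golay type) fit: a centered quadratic over a
5 ms window in the interior, and a one-sided *cubic* over a three-fold
window where a centered window does not fit. The boundary treatment
matters: for a saturating rise the maximal slope sits exactly at the
onset, and a moving-average-plus-central-difference scheme is biased low
there by roughly `1 − (2τ/w)(1 − e^{−w/2τ})` (about 11% for a 20 ms time
constant and 5 ms window) no matter how clean the data. Raising the local
order and widening the support at the boundary removes that bias while
keeping the noise amplification of an off-centre derivative acceptable.
The window width is configurable (`smooth_ms`); a rise shorter than the
window is an error suggesting a smaller window. MRFD is invariant to
baseline offsets by construction, and is reported in mN·ms⁻¹ together
with `MRFD/F_max`.

**Force–frequency.** Per-frequency peak total forces are
passive-subtracted and divided by the maximal active force across
frequencies, so the curve's maximum is exactly 1. The verbal protocol
("subtract passive … divide total") is self-contradictory; dividing the
passive-subtracted force is the consistent reading and the default, with
`mode = "total"` for the literal one.

**Fatigue.** The fatigue index is `100·(1 − F_end/F_max)` over the peak
forces of a repeated-contraction run; `F_end` defaults to the final
contraction's peak (`f_end_rule = "mean_last_k"` averages the last k).
Peaks come from per-event windows or are inferred from a fixed 1 s
stimulation period.

## Morphometry

Closed forms, with the constants as named, overridable defaults rather
than literals: optimum sarcomere length 2.2 µm, muscle density
1.0597 g·cm⁻³, myonucleus length 12 µm, section thickness 10 µm.

- serial sarcomere number = fiber length / mean sarcomere length;
- optimum fiber length = sarcomere number × 2.2 µm;
- muscle volume = mass / density (mg and mm³ are conveniently conformal
  at g·cm⁻³ densities);
- PCSA = volume / optimum fiber length. Using the *optimum* fiber length
  (rather than the measured mean) is the package default since volume is
  also referenced to the optimum condition; `morphometry_summary()` takes
  a fibers table either way.
- myonuclei per fiber: a section of thickness `D_s` intersects a nucleus
  of length `L_m` with probability `(L_m + D_s)/L_f`, so the true count is
  `N_{n,s} · L_f/(L_m + D_s)`. The Monte-Carlo generator
  (`sample_nucleus_profiles()`) samples exactly this geometry and the
  test suite asserts agreement within 2% at 10⁴ slabs.
- myonuclear domain = fiber CSA / (nuclei per mm fiber). The units of
  this conventional definition are odd (area over a linear density); it
  is implemented literally and documented as such.

Every function carries units in its argument names and rejects
physiologically impossible magnitudes (a sarcomere length of 0.0022
"µm" — i.e. a mm value — is an error, not a silent million-sarcomere
fiber). Per-muscle serial sarcomere numbers are means over the proximal
and distal fiber groups; pooling by region means (default) or grand mean
is a flag.

## Histomorphometry

Inputs are label masks (fibers) and binary masks (connective tissue) with
an explicit pixel size — segmentation of raw stains is out of scope.
Areas are pixel counts × pixel size²; perimeters are 4-neighbour
crack-length counts × pixel size. Edges on the image border are *not*
counted: a fiber clipped by the ROI is treated as continuing beyond it,
so cropping does not inflate perimeters (and therefore does not deflate
`L_e`, which divides by the mean perimeter). Crack-length overestimates
oblique boundaries by up to √2; it is used consistently on both synthetic
truth and measurement, and the acceptance band on `L_e` (15%) absorbs the
residual.

Fiber typing thresholds per antibody channel: user-supplied or Otsu with
a bimodality guard (the split must explain ≥ 80% of the channel variance,
otherwise the channel has no positive fibers — an all-negative channel
would otherwise be split down the middle of its background noise).
Multi-positive fibers are hybrids labeled with the sorted combination.
The antibody→isoform mapping is a configurable table; the default follows
the staining panel order (BAD5→I, SC-71→IIA, 6H1→IIB, BF-F3→IIX), and
the common convention with the last two swapped is one argument away.

SDH activity converts gray values to absorbance against a user-supplied
blank, `A = −log10(I/I0)`, divided by section thickness and incubation
time; the incubation time has no default because it is a protocol
parameter. Perimysium thickness is sampled every 25 µm of arc length
along annotation paths (polyline CSVs standing in for manual
measurement), as twice the distance from the sample point to the nearest
non-connective pixel — the medial-axis reading for a path along the band
midline. Samples outside connective tissue are dropped with a warning.
Whether endomysium `L_e` is averaged over ROIs before or after the
perimeter division is itself ambiguous; the batch wrapper averages
ROI-level `L_e` values.

## Expression

2^−ΔCt with ΔCt = Ct_target − Ct_reference by default. The protocol
sentence literally reads the other way around; since that inverts every
ratio, the orientation is an explicit flag
(`orientation = "reference_minus_target"`) rather than a silent choice.
Replicates are averaged on the Ct scale *before* exponentiation;
duplicates more than 0.5 cycles apart are flagged, not dropped. No
efficiency correction (Pfaffl) is applied — plain 2^−ΔCt is the method
implemented.

## The synthetic-data generators

`ground_truth()` fixes a simulated muscle: the active length–force curve
is a scaled, shifted power of a cosine — exactly zero at `L_slack`,
exactly `F_opt` at `L_opt`, single-peaked, and deliberately *not* a
polynomial, so the fitting stage is exercised under model mismatch rather
than in a self-fulfilling round trip. The default exponent
(`curve_shape = 1`) gives a finite, nonzero slope at slack, matching the
transversal x-axis crossing of the classic sarcomere length–tension
ascending limb; a tangential zero (exponent 2) would make the slack
length ill-conditioned for any estimator. The passive curve is generated
in the same family the fitter uses by default, so zero-noise recovery is
exact by construction. Defaults are the adult wild-type soleus scale
(`F_opt` 294 mN, `L_opt` 15.2 mm, `L_slack` 11.1 mm, tibia 18.89 mm for
normalization examples).

Noise is iid Gaussian on each force reading (`noise_sd`, default 3 mN; a
heteroscedastic option scales the sd with the square root of the
noise-free force). No noise magnitude is reported for the instrument this
emulates, so the default is a plausible transducer-level figure and every
test states the level it uses — typically 2% of `F_opt`.

Tetanus traces rise as `F_opt(1 − e^{−t/τ})` (τ default 20 ms) over a
flat pre-stimulus baseline: the analytic maximal slope `F_opt/τ` at onset
is the oracle for the MRFD estimator. Fatigue runs decay as
`F0(a + (1−a)e^{−rk})` with asymptotic fraction `a` (default 0.84) and
rate `r` (default 0.05 per contraction, a ~20 s time constant plausible
for a 2-minute 1-Hz soleus protocol), giving a closed-form fatigue index.

Synthetic cross-sections are Voronoi tessellations of jittered-grid seeds;
the endomysial seam is carved where the perpendicular distance to the
bisector of the two nearest seeds is below half the endomysium thickness,
so the seam has true metric width. The per-fiber truth table (areas,
perimeters) is computed from the generated masks themselves, which is
what makes "measured areas equal truth exactly" a construction invariant
rather than an estimate.

What the generators do **not** emulate: tendon compliance and pennation
(forces are muscle-level), twitch kinetics, stimulation artifacts,
baseline drift, fiber cross-section anisotropy, staining variability
beyond Gaussian channel intensities, or section-to-section registration
error. Passing recovery tests therefore demonstrates estimator
correctness under idealized measurement statistics, not robustness to
every artifact of a live preparation.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 100 simulated length
series of 11 lengths (0.5 mm steps, noise 2% of `F_opt`) for recovery
medians; 200 seeds for the noisy-cubic order-selection rate; 100 random
quartics against a 0.1 µm grid for optimum extraction; 10⁴ Monte-Carlo
slabs for the nuclear-count expectation; a 100-fiber Voronoi section for
histomorphometry; 120 contractions for fatigue. These sizes put the
Monte-Carlo error well below each assertion's tolerance while keeping the
whole suite in the tens of seconds. Every generator is bit-reproducible
given its spec and seed; `run_study()` writes a provenance record (seed,
config hash, package version) and reruns byte-identically.

## Known limitations

- The polynomial active-curve family is a descriptive fit: `L_mas` is an
  extrapolated x-intercept and inherits polynomial wiggle; the 25%
  extrapolation cap and the "slack not bracketed" error make the failure
  mode explicit instead of silent.
- `L_e` is an area-over-perimeter summary; it matches the half-thickness
  geometric expectation only for seams shared between two fibers and
  degrades at triple junctions and coarse pixel sizes.
- The fatigue index depends on the final-contraction convention for
  `F_end`; with noisy peaks the protocol maximum is upward-biased, which
  inflates the index by a noise-dependent amount.
- Group-level inference (ANOVA across animals, GEE) is deliberately out
  of scope; the package stops at per-muscle derived variables.
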