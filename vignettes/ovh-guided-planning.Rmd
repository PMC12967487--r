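---
title: "OVH-guided dose-constraint prediction: models, conventions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OVH-guided dose-constraint prediction: models, conventions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovhplan)
```

## The problem and the model

Inverse planning for breast radiotherapy needs per-organ dose–volume
objectives before optimization starts, but how much heart and ipsilateral-lung
sparing is *achievable* differs from patient to patient: it is largely
determined by how closely each organ wraps the planning target. `ovhplan`
captures that geometry with the overlap volume histogram (OVH),

$$\mathrm{OVH}_{O,T}(d) \;=\; \frac{\bigl|\{\,p \in O : d(p,T) \le d\,\}\bigr|}{|O|},$$

the cumulative fraction of organ $O$ within signed distance $d$ of target
$T$. Its generalized inverse $L_x$ (mm) — the isotropic expansion of the PTV
needed to cover $x\%$ of the organ — is the patient-specific geometric
predictor. The dosimetric response is the DVH quantile $D_x$ (Gy), the dose
received by the hottest $x\%$ of the organ. Within a treatment stratum the two
are modeled linearly, $D_x = a\,L_x + b$, fitted by ordinary least squares
with $r^2$ equal to the squared Pearson correlation (identical for simple
regression, so a single number is stored) and a two-tailed zero-slope $t$ test
on $n-2$ degrees of freedom.

Calibration never pools strata: left/right laterality and
post-mastectomy (PMRMRT, conventional 50 Gy in 25 fractions, chest wall plus
supraclavicular target) versus breast-conserving (BCRT, hypofractionated,
chest wall only) plans have systematically different geometry–dose
relationships, so `fit_cohort_models()` refuses mixed tables. The sixteen
shipped reference models (`bundled_models()`) cover lung $D_{50}/D_{35}/D_{25}$
in all four strata and heart $D_{10}/D_5$ in the left-sided strata; right-sided
strata carry no heart models because the heart is distant from right-sided
targets. Bundled models store the printed coefficients, $r^2$ and the p-value
*bound* (`"<0.001"`) verbatim; only models fitted by this package carry exact
p-values and an observed $L$ range.

Predictions feed the constraint generator: each predicted $D_x$ becomes an
overdose-style objective $V_{\hat D} \le x\%$ with
$\hat D = \min(\text{prediction}, \text{clinical ceiling at that volume})$, so
a generated constraint can tighten but never relax the clinical limits
(lung $V_{5} \le 50\%$, $V_{10} \le 35\%$, $V_{20} \le 25\%$; left-sided
additionally heart $V_{20} \le 10\%$, $V_{40} \le 5\%$ and a mean-heart-dose
cap). Mean dose has no $L_x$-based predictor — geometry indexes a volume
fraction, not the whole integral — so $D_\mathrm{mean}$ entries come only from
the ceilings. The mean-heart ceiling is quoted clinically as a 6–8 Gy range;
the package uses the lenient 8 Gy bound as the default cap, since the
constraint generator's job is to encode hard limits, with tighter goals coming
from the predictions themselves. Relations are normalized to `<=`: planning
systems treat strict and non-strict overdose bounds identically.

## Distance and curve conventions

**Signed distance.** `signed_distance_field()` returns, at every voxel
center, $+$(distance to the nearest target voxel center) outside the target
and $-$(distance to the nearest non-target voxel center) inside. Distances are
physical (mm) and respect anisotropic spacing; the transform is an exact
separable lower-envelope Euclidean distance transform implemented in C++, so
it agrees with a brute-force pairwise minimum to floating-point precision (the
test suite asserts exactly this). The grid is treated as padded by one
background layer, so a target filling the whole grid still yields finite,
non-positive values. Center-to-center distances (rather than distances to an
interpolated surface) were chosen because they make the oracle comparison
exact and match what the standard image-processing transforms produce; for
thoracic organs essentially all distances are positive and several voxels
large, so the sub-voxel surface offset is invisible downstream. Voxel centers
sit at `origin + (index − 1 + 0.5) · spacing`; masks are never resampled
implicitly (an explicit nearest-neighbor `resample_mask()` and trilinear
`resample_dose()` are provided — occupancy is categorical, dose is smooth).

**OVH curves.** Bin edges are multiples of the bin width, starting one bin
below the closest organ voxel (fraction 0) and ending at the first edge
covering the whole organ (fraction exactly 1). `l_x()` interpolates linearly
between adjacent bins; `l_x(curve, 100)` is the final distance. The default
export/plotting bin is 1 mm, so interpolation error is bounded by one bin.

**DVH curves.** Cumulative only (`fraction receiving ≥ t`), bins from 0 Gy in
0.05 Gy steps to one bin above the maximum structure dose, so curves start at
1 and end at exactly 0. `d_x()` interpolates linearly between bins with one
deliberate exception: the terminal bin's descent to zero is a binning
artifact — the true curve is identically zero above the maximum dose — so a
quantile landing there resolves to the bin edge at or below the maximum
(ties toward the lower dose). This makes a perfectly uniform field return
$D_x = $ the uniform dose for every $x$, hence $HI = 0$ exactly, instead of a
spurious half-bin spread.

**Quantile extraction for calibration.** Voxel distances concentrate on
lattice values (there are only so many integer offset combinations), so the
distance ECDF has atoms. Linear interpolation across a coarse bin smears those
atoms and biases $L_x$ by a noticeable fraction of the bin — harmless for
display, but a systematic error source when the extracted pairs feed a
regression. `phantom_metrics()` therefore samples the OVH at 0.05 mm and the
DVH at 0.02 Gy, making metric-extraction error a few hundredths of a Gy,
negligible against 1 Gy dose noise.

**Plan indices.** $CI = TV_P^2/(V_{PTV}\,V_P)$ uses voxel-count volumes with
no surface smoothing; an empty prescription isodose is a hard error with a
diagnostic. $HI = (D_2 - D_{98})/D_P$.

## Predictions, clamping, and degenerate statistics

A regression line extended to extreme geometries can go negative;
`predict_dx()` clamps at 0 Gy and flags the clamp rather than failing, and
flags any $L_x$ outside the fitted range as extrapolation (published models
carry no range, so their flag is `NA`). Clamping-plus-warning was chosen over
silent extrapolation because a degenerate 0 Gy objective should be visible to
the planner, and the flag propagates into the constraint set.

`compare_cohorts()` hand-codes the paired $t$ statistic
($\bar d / (s_d/\sqrt n)$ on $n-1$ df) so the degenerate constant-difference
case has defined behavior: identical arms give $p = 1$, an exact nonzero shift
gives $p = 0$. (The stock t-test errors on constant data; it serves as the
independent cross-check in the tests for non-degenerate inputs.) Percent
reductions are reported at one decimal place in the CSV reports, matching
conventional clinical reporting.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` builds analytic primitives on a 96×96×64 grid at 2.5 mm
isotropic spacing (240×240×160 mm — an adult thorax at a typical planning
resolution, chosen so OVH curves are stable while a phantom builds in well
under a second): two ellipsoidal lungs (default semiaxes 38/52/62 mm), a
spherical heart left of midline carved out of the lungs with a 3 mm
pericardial margin, and a chest-wall PTV defined as the set of voxels whose
distance to the ipsilateral lung lies in
$[\text{gap}_\text{lung}, \text{gap}_\text{lung} + \text{thickness}]$,
restricted to the anterolateral sector, bounded by an implicit 112 mm body
cylinder, kept at least $\text{gap}_\text{heart}$ from the heart, plus a
supraclavicular block for post-mastectomy plans. Primitives are analytic
precisely so gap and laterality claims are verifiable by brute force; a seeded
±5% size and ±2 mm position jitter makes cohorts of distinct, reproducible
patients.

`generate_dose()` assigns the prescription inside the PTV and
$f(\text{signed distance})$ outside — linear ($P - m\,d$, default
0.9 Gy/mm, a typical tangential-field penumbra-plus-scatter scale) or
exponential ($P\,2^{-d/h}$) — plus optional additive Gaussian noise truncated
at 0 Gy (the scatter around published geometry–dose calibrations is roughly
homoscedastic, so additive noise is the right first-order emulation; the
default cohort noise of 1 Gy reproduces that order of spread). With zero
noise, dose is an exact monotone function of distance, which forces
$D_x = f(L_x)$ for every organ and every $x$ — the package's central
cross-module correctness property — and makes the induced cohort law exactly
$D_x = P - m\,L_x$, so regression recovery has known ground truth.
Cohort anatomy is sampled uniformly from realistic adult ranges
(chest-wall thickness 10–20 mm, heart radius 25–35 mm, lung scale 0.85–1.15,
lung gap 2–6 mm, heart gap 5–25 mm).

What the phantom does *not* emulate: beam/arc geometry and its anisotropic
dose shadows, buildup and low-dose bath, respiratory motion, CT appearance,
and the inter-planner variability that real calibrations absorb. Passing
tests therefore demonstrate that the geometry→dose→calibration machinery is
self-consistent and numerically exact — not that the shipped clinical
coefficients transfer to any particular institution's data, which requires
external validation on real plans.

## Validation design and problem sizes

The test suite checks, among others: exact agreement of the distance
transform with an exhaustive pairwise oracle on random anisotropic masks
(and, in the acceptance suite, on 200 random pairs of up to 20³ voxels);
the distance-monotone equivalence $|D_x - f(L_x)|$ within one OVH bin mapped
through the falloff slope plus one DVH bin; recovery of the generating slope
within three standard errors and noise-free $r^2 \ge 0.999$ on a 50-phantom
cohort; the analytic $r^2$ expectation
$\mathrm{Var}(aL)/(\mathrm{Var}(aL)+\sigma^2)$ on a 200-pair synthetic fit;
bit-identical JSON round trips of the bundled calibrations (17-significant-
digit serialization); and the closed forms $CI = 1$, $CI = 0.64$ for the
80/100/100 configuration, $HI = 0$, and the DVH-integral identity for mean
dose. These sizes keep the whole suite in a few minutes on one core while
leaving every estimate's sampling error far below the tolerance it is tested
against.

## Known limitations

- Distances are voxel-center based; sub-voxel (mesh) surface distances and
  partial-volume weighting of edge voxels are out of scope, so OVH values
  carry up to half a voxel-diagonal of surface uncertainty.
- DICOM RT-STRUCT/RT-DOSE are not read directly; convert to NIfTI/NRRD first.
- The linear model is deliberately simple and interpretable; genuinely
  nonlinear anatomy–dose relationships (very small organs, unusual target
  extensions) are outside its reach.
- Published cohort tables occasionally print obvious typos (homogeneity-index
  entries shifted by a factor of 10, e.g. 0.0104 for 0.104); the bundled
  assets reproduce coefficients as printed and never use those HI entries
  numerically.
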