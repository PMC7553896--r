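---
title: "How calculation settings shape radiomic feature reliability and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How calculation settings shape radiomic feature reliability and prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomic studies extract quantitative features — shape, intensity and
texture descriptors — from delineated tumour volumes on CT and relate them
to clinical endpoints. Several mature software platforms compute nominally
the same features, but each ships its own *calculation settings*: how
continuous intensities are discretised into grey levels, which displacement
vectors feed the grey-level co-occurrence matrix (GLCM), what neighbourhood
distance the neighbourhood grey tone difference matrix (NGTDM) uses. Two
platforms can therefore disagree substantially about the value of "the same"
feature on the same image, which undermines both reproducibility and any
prognostic model built on those features.

`radharm` turns this situation into a testable pipeline. A **settings
profile** is a complete set of calculation settings and plays the role of a
rater: extracting the same 17-feature panel under several profiles, the
package quantifies their agreement with intraclass correlation coefficients
(ICC) and screens every feature against survival with univariable Cox
models, under each profile. Because no public imaging accompanies this kind
of analysis, a synthetic phantom generator stands in for the clinical
volumes; everything downstream of the generator is the same code a user
would run on real NIfTI images.

## The feature panel

The 17 canonical features are the panel shared by the major platforms:

* **Shape (3):** volume (mesh-based, with voxel counting reported
  alongside), surface area (mesh), and sphericity
  $\Psi = \pi^{1/3}(6V)^{2/3}/A$.
* **First order, raw intensity (4):** minimum, maximum, mean, and the
  population standard deviation of the masked voxels.
* **Histogram (1):** skewness of the discretised grey levels,
  $\gamma_1 = m_3 / m_2^{3/2}$ with population moments.
* **GLCM (6):** correlation, contrast, angular second moment, joint
  entropy, difference average, inverse difference, computed from a single
  merged symmetric co-occurrence matrix.
* **NGTDM (3):** busyness, coarseness, contrast.

Population (biased) moments are used throughout the first-order and
histogram definitions, matching the convention of the standardisation
initiative that defines this nomenclature. The panel splits into a
settings-*independent* part (shape and raw first order — no preprocessing
is applied, so these cannot depend on the profile) and a
settings-*dependent* part (skewness and all nine texture features inherit
the discretisation, directions and distances). That partition is the
mechanism behind every result the pipeline produces.

## Settings profiles

`builtin_profile()` ships five profiles. Four reproduce platform defaults:
fixed-bin-number discretisation over a fixed Hounsfield range (400 bins
over [−1000, 3000], or 256 bins over [0, 4096] with a different GLCM block
of 100 bins over [0, 2100]), fixed bin width 25 HU anchored at the ROI
minimum, and fixed bin width 25 HU anchored at 0 with values clamped into
[0, 500] and only the four in-plane co-occurrence directions. The fifth,
`harmonised`, uses 64 grey levels between the ROI minimum and maximum, all
13 unique 3D directions at offset 1, symmetric accumulation, and NGTDM
distance 1.

```{r}
library(radharm)
builtin_profile("harmonised")
builtin_profile("ibex_default")
```

Three structural choices deserve explanation:

* **Per-family discretisation blocks.** One platform's defaults use
  different bin counts and bounds for the histogram and the GLCM, so a
  profile carries `disc`, `glcm_disc` and `ngtdm_disc` blocks (the latter
  two default to the first). A single-block model could not reproduce that
  platform's behaviour.
* **Merged matrices.** Profiles with several offsets (one platform lists
  offsets 1, 4 and 7) accumulate all displacements into one co-occurrence
  matrix rather than averaging per-offset features. The platforms do not
  document their aggregation; a single merged matrix keeps the downstream
  feature contract uniform, and the choice is recorded here as an open
  modelling decision rather than a claim about the original software.
* **Four directions are 2D.** A four-direction GLCM only exists in-plane;
  that profile applies the four canonical 2D directions slice-wise and
  merges across slices.

Profiles serialise to YAML and round-trip exactly, so a profile file is a
complete, shareable description of a platform emulation. The
divide-by-zero guard `eps_guard` is stored per profile: how a platform
handles degenerate texture is itself a calculation setting.

## Discretisation

All three dialects use half-open bins with a closed top edge, so the
masked maximum lands in the last bin and the level histogram always
conserves the voxel count. Out-of-range values under fixed bounds are
clamped into the end bins, never dropped. Fixed-bin-number over the ROI
range is invariant under affine intensity rescaling; fixed bin width is
covariant under shifts by whole bins. A flat ROI maps every voxel to
level 1 and flags the result `degenerate`, and every texture feature then
takes an explicit homogeneous-ROI convention (GLCM: contrast 0, ASM 1,
entropy 0, difference average 0, inverse difference 1, correlation 1;
NGTDM: busyness 0, coarseness capped at $10^6$, contrast 0). Flat regions
are legitimate inputs — synthetic edge cases and post-contrast uniform
lesions both produce them — so they must flow through the pipeline rather
than crash it.

## The surface mesh

Shape features need a triangulated surface. The mask is meshed at
iso-level 0.5 after one-voxel zero padding, using marching tetrahedra over
the Freudenthal six-tetrahedron decomposition of each dual cube. Because
every cube is split along the same main diagonal, neighbouring cubes split
their shared faces identically and the mesh is watertight by construction;
triangle orientation is derived programmatically from the inside/outside
corner centroids, so the implementation carries no hand-copied case
tables and its correctness is checked by closure and analytic-volume
tests.

The raw mid-point surface of *any* binary marching method is ragged at the
voxel scale, and that raggedness inflates the metric surface area by a
resolution-independent factor (about 9% for classic marching cubes on a
digital ball, more for tetrahedra). Volume converges, area does not — so
sphericity of a digitised sphere would plateau near 0.92 instead of
approaching 1. The package therefore applies a shrink-free Taubin
smoothing pass (uniform umbrella weights, $\lambda = 0.5$, $\mu = -0.53$,
80 iterations by default) to the mesh before measuring it. On digital
balls of radius 12–28 voxels this yields sphericity 0.98–0.99 with volume
within about 1% of the analytic value; on a $10^3$ cube the surviving
error is the genuine corner chamfer (a few percent of area). Setting
`smooth_iterations = 0` recovers the raw marching surface; the default is
a deliberate trade of exact flat-face geometry for convergent metrics on
the rounded shapes that tumours actually are.

## Texture matrices

The GLCM accumulates level pairs over every profile displacement
(direction × offset), counts each pair in both orders, and merges
everything into one matrix; only pairs whose both voxels lie in the mask
count. Feature formulas act on the joint probabilities, so empty grey
levels are irrelevant and the matrix is stored over the occupied level
range. The NGTDM neighbourhood is the full Chebyshev-distance-$d$ cube
minus the centre, intersected with the mask; a voxel with no masked
neighbour is excluded from the valid count. Both builders are vectorised
array-shift implementations, and both are tested cell-by-cell against
brute-force enumeration on small grids — the enumeration oracle, not the
production path, defines correctness.

## Reliability analysis

Between-profile agreement uses the single-measure, absolute-agreement,
two-way ICC. From the two-way ANOVA mean squares (subjects MSR, raters
MSC, residual MSE):

$$\hat\rho = \frac{MSR - MSE}{MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE)}$$

with the standard F-based 95% confidence interval for this form. The
mixed- and random-effects two-way models share this point estimate, so the
"mixed" phrasing common in reliability reports is implemented without loss.
Negative estimates and bounds are truncated at zero and the upper bound is
capped at one. Two degenerate regimes get explicit conventions, both
flagged: columns that agree exactly (ICC 1, CI (1, 1) — this happens by
construction when profiles share all settings, because the engine is
deterministic) and matrices with no variation at all. When the raw
estimate is strongly negative the F interval can lose numerical meaning;
the affected bound then falls back to its uninformative limit and the
result is flagged `ci_degenerate`.

Reliability categories use the conventional 0.5 / 0.75 / 0.9 thresholds
(poor / moderate / good / excellent). Published analyses stratify "the ICC
and its CI" without saying what to do when the interval straddles a
boundary; the package takes the conservative reading — the category of the
CI *lower bound* — and additionally reports the point-estimate and
upper-bound categories with a straddle flag, so a user can apply either
rule. Boundary values go to the lower category. Features constant over all
subjects and raters carry no reliability information and are excluded from
the "x / 17" category counts, which always total the analysable features.

Subjects with a missing value for any rater are dropped listwise (complete
blocks are required by the ANOVA), with the dropped count reported.

## Survival screen

Each feature is standardised to mean 0, SD 1 (sample SD; the unit-SD
contract is what matters) within each profile, then fitted alone in a Cox
proportional-hazards model with Efron tie handling — the default of the
standard survival toolchain that reliability studies in this area use.
Wald p values are binned at 0.05 and 0.1 for the heat-map view. No
multiple-testing correction is applied by default, matching the screening
character of the analysis; Benjamini–Hochberg adjustment is available as
an opt-in column. Constant features and monotone-likelihood fits are
recorded in the output cells instead of aborting the screen.

## The synthetic cohort

`generate_phantom()` builds CT-like tumour volumes: an ellipsoidal
(optionally lobulated) mask inside an anisotropic grid (defaults: 1 mm
in-plane, 3 mm slices), filled with a base intensity of 45 HU plus a
spatially correlated Gaussian field (Gaussian-filtered white noise,
rescaled to a target SD — one interpretable knob, the correlation length,
moves every texture feature predictably) plus independent voxel noise. An
optional deterministic radial gradient emulates centre-to-rim contrast
enhancement. Default geometry (semi-axes 18 × 14 × 12 mm, ≈ 13 mL) and
intensities (texture SD 25 HU, noise SD 10 HU) are in the range of
contrast-enhanced head-and-neck tumours on planning CT. Every generator is
a pure function of its spec and seed, restores the caller's RNG state, and
reproduces bitwise.

`generate_cohort()` draws event times from an exponential hazard
$h_0 e^{\beta z}$ with administrative censoring at the follow-up horizon;
$h_0$ is calibrated by root finding so the *expected* event count hits the
target. The defaults — 108 subjects, horizon 2.2 years, 28 expected
events — mirror the size and event rate of a typical single-centre
head-and-neck cohort, as configuration defaults rather than a claim of
distributional fidelity. `generate_ratings()` produces subjects × raters
matrices with known subject, rater-bias and noise variance components, the
ground truth for the ICC tests.

What the phantoms deliberately do not model: scanner acquisition and
reconstruction effects, contour variability between observers, non-Gaussian
tissue mixtures, and any spatial correlation between shape and texture.
Passing tests on phantoms therefore demonstrate that the *pipeline
mechanics* (settings sensitivity, agreement statistics, screening) behave
as designed — not that any particular clinical effect size would
reproduce.

## The two demonstrations

**Harmonisation drives reliability.** On a cohort of varied phantoms,
profiles that share the harmonised settings agree exactly (excellent ICC
for all 17 features), while heterogeneous platform defaults keep excellent
agreement only for the seven settings-independent features; the ten
discretisation-dependent features degrade, many to the poor category,
because a 400-bin fixed-range discretisation and a 25-HU bin width produce
texture values on entirely different scales. Cloning a profile with a
single perturbed setting (64 → 32 bins, a stand-in for a version change)
degrades only the dependent features. Both patterns are asserted
qualitatively — category counts and the dependent/independent partition —
never as clinical effect sizes, which would require the original scans.

**Settings can invert hazard direction.** `demo_inversion()` builds
phantoms whose smooth-component amplitude varies across subjects over a
fixed fine-noise floor, and plants a hazard increasing with the *observed
ROI intensity range* (β = 0.9 per SD, the mediating variable itself).
Under range-adaptive discretisation a wider range compresses the fixed
fine texture into fewer of the 64 bins, so joint entropy falls as the
range grows; under a fixed wide-range discretisation the occupied bin
count grows instead, so joint entropy rises. The same subjects with the
same outcomes then give a joint-entropy hazard ratio below 1 under
harmonised settings and above 1 under the fixed-range default — the
feature changed the biophysical property it measures when the settings
changed. The long texture correlation length (5 voxels) keeps the
smooth-field contribution to entropy small so the mechanism dominates
realization noise.

```{r}
inv <- demo_inversion(seed = 1)
inv$screen[, c("profile", "hr", "p", "bin")]
```

## Numerical choices and edge cases

* Bin edges: half-open, top edge closed; maximum maps to the last bin.
* Degenerate ROIs (flat, single-voxel, no valid texture pairs) flow
  through every stage via flagged conventions instead of errors; genuine
  input errors (empty masks, constant features in the screen, too few
  events) fail fast with specific messages.
* ICC near-degeneracy: exact agreement and zero variance are detected at
  relative tolerance $10^{-10}$ on the mean squares before the F interval
  is attempted.
* Mesh: closure (every directed edge once, every undirected edge twice) is
  checked before volume integration; `mesh_volume()` refuses open meshes.
* All tabular outputs are plain CSV; a study re-run with the same
  configuration and seed reproduces its files byte for byte.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 2–14 phantoms
on 40–64 voxel grids for the reliability mechanisms and the full 108-subject
cohort for the inversion demonstration, with 1000-subject ratings matrices
and survival cohorts for the statistical recoveries. These sizes were
chosen as the smallest at which each qualitative claim is stable across
seeds; all of them run on a single CPU in a few minutes.

## Known limitations

* The platform profiles emulate documented *settings*, not platform code:
  undocumented implementation details (aggregation across offsets,
  resegmentation, interpolation) are out of scope, so a profile named
  after a platform is a settings emulation, not that platform.
* Surface area of shapes with sharp edges is mildly underestimated by the
  smoothed mesh (corner chamfer); raw meshes are available where exact
  polyhedral geometry matters.
* The ICC assumes complete blocks after listwise deletion and Gaussian-ish
  residuals; heavy-tailed features (NGTDM busyness spans orders of
  magnitude) can make the F-based interval optimistic.
* Only single-covariate Cox models are provided, by design: the screen is
  a univariable analysis and multivariable modelling is out of scope.
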