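---
title: "Quantitative cardiac CT perfusion with ccperf: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cardiac CT perfusion with ccperf: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dynamic contrast-enhanced cardiac CT perfusion (CCTP) follows an iodine
bolus through the heart over a ~30-second acquisition and asks a
quantitative question: how much blood reaches each gram of myocardium per
minute? The answer — myocardial blood flow (MBF), in mL·min⁻¹·(100 g)⁻¹ —
discriminates two conditions that look identical on anatomical imaging
alone. A territory downstream of an obstructive epicardial stenosis shows a
focal perfusion deficit (flow-limiting disease), while coronary
microvascular disease (MVD) shows diffusely reduced flow with clean
epicardial arteries. Coronary CT angiography (CCTA), graded with CAD-RADS
(0–5, grade ≥ 3 deemed obstructive), supplies the anatomy; `ccperf`
supplies the flow and the logic that combines both.

The package implements the full processing chain — aorta detection,
temporal registration, segmentation, beam-hardening correction, kinetic
model fitting with superpixel aggregation, bullseye polar maps with AHA-16
segment statistics, and cohort-level threshold derivation and patient
classification — together with a digital phantom and synthetic cohort
generator that provide exact ground truth for every stage. No patient data
are used anywhere; all empirical statements in this vignette are the ones
the test suite and `scripts/acceptance.R` themselves compute.

## The kinetic model

Tissue enhancement is modelled with a simplified Johnson-Wilson
(one-compartment) tissue model with three free parameters — flow, arterial
delay and a washout decay constant:

$$C_t(t) \;=\; f \int_0^{t} C_a(\tau - \Delta)\, e^{-k\,(t-\tau)}\, d\tau,
\qquad f = \frac{\mathrm{MBF}}{6000}\ \mathrm{s}^{-1},$$

where $C_a$ is the arterial input function (AIF) measured in the aorta and
$C_t$ the myocardial time–attenuation curve (TAC), both in HU enhancement
above their pre-contrast baselines. The factor $1/6000$ converts
mL·min⁻¹·(100 g)⁻¹ to s⁻¹ assuming tissue density 1 g/mL. This convolution
with an exponential impulse response is our concrete realisation of the
"simplified Johnson-Wilson model with three free parameters"; the published
description of that estimator does not print its equations, so the package
documents its own form rather than claiming equation-level fidelity to it.

The convolution is evaluated by an exact trapezoidal recursion
($O(n)$ per curve, identical to trapezoidal quadrature at every node), so
forward simulation and fitting share no approximation beyond the time grid
itself.

### Fitting

`fit_rpm1()` minimises the residual sum of squares over
$(\mathrm{MBF}, \Delta, k)$ in two stages:

1. **Coarse grid.** Delay is scanned in 0.5 s steps and $k$ on 16
   logarithmically spaced points (plus $k = 0$); at each node the model is
   linear in MBF, so the flow is solved in closed form
   (`closed_form_mbf()`, a scalar projection clipped to bounds). The grid
   basis can be precomputed once per study (`rpm1_grid()`) and shared
   across thousands of voxel fits.
2. **Refinement.** Bounded L-BFGS-B from the best node. The refined fit is
   accepted only if it does not worsen the grid optimum, so the final RSS
   never exceeds the coarse-grid best.

Default bounds are a generous physiologic envelope for stress perfusion:
MBF ∈ [0, 600] mL·min⁻¹·(100 g)⁻¹, delay ∈ [0, 10] s, k ∈ [0, 1] s⁻¹. On a
zero-noise truth lattice (MBF 50–400, delay 0–6 s, k 0.05–0.3 s⁻¹, 1 s
frames over 30 s) the worst-case relative MBF error is about $10^{-5}$,
i.e. the two-stage search does not get trapped in local basins on clean
data. The fit returns a classed model object with the standard methods
(`coef`, `summary`, `predict`, `residuals`, `plot`, `simulate`).

### Superpixel aggregation (SLICR)

Voxelwise fitting is noise-limited: at 20 HU frame noise the voxelwise MBF
RMSE on the phantom is roughly four times that of the superpixel route.
`slic_supervoxels()` clusters myocardial voxels with a SLIC-style iterative
scheme on the joint feature $[\,w_s\,(x,y,z)/S,\ \mathrm{TAC}/\max \mathrm{TAC}\,]$
(seeds on a regular lattice, 2S search windows, ≤ 10 iterations, then a
connectivity pass that keeps each cluster 26-connected). Two choices
deserve a note:

* **TAC scaling.** TACs are scaled by the mask-wide peak enhancement, not
  per-voxel peaks. Per-voxel normalisation would erase exactly the
  amplitude differences that distinguish hypo- from normally-perfused
  tissue, making flow-coherent clustering impossible; a single global scale
  keeps spatial and enhancement feature magnitudes commensurate while
  preserving contrast between sectors.
* **Median cluster TAC.** `slicr_mbf_map()` fits the voxelwise *median*
  TAC of each cluster and broadcasts the fitted MBF to members. The median
  is the robustness ingredient: single outlier voxels (noise spikes,
  partial volume) do not drag the cluster curve. Whether the original
  SLICR formulation fits median curves or aggregates per-voxel fits is not
  printed in the sources available to us; median-TAC fitting is this
  package's documented choice, with ~25 voxels per cluster and spatial
  weight 0.2 as defaults.

## Beam-hardening correction (ABHC)

Iodine concentrates strongly in the ventricular cavity during the bolus
and hardens the beam, producing a cupping bias across the myocardium that
tracks the instantaneous enhancement. The phantom simulates the artifact as
an enhancement-scaled radial polynomial,
$\mathrm{bias}(r,t) = E(t)\sum_{i=1}^{3} c_i (r/R)^i$, and the corrector
searches the same family with negated sign. This symmetry is a deliberate,
documented simplification: it makes exact inversion attainable in
simulation and is not a claim about scanner physics; on real data the
polynomial family is a first-order model of cupping.

The correction coefficients minimise an image-domain cost
(`bh_cost()`): the mean within-myocardium HU variance per frame (spatial
term, mean-removed and therefore invariant to global HU offsets) plus
λ times the mean squared frame-to-frame change of the mean myocardial HU
over the *pre-contrast* frames. The temporal window is restricted to
pre-contrast frames because that is the only segment where true myocardial
enhancement is genuinely flat; late-washout frames still carry real
physiological slope, and penalising change there would reward corrections
that cancel genuine signal. For the enhancement-scaled correction family
the temporal term is consequently near-inactive (the artifact vanishes
where $E(t) \approx 0$) and the spatial term drives the search; the
temporal term guards against corrections injected through a mis-estimated
enhancement curve. λ defaults to 1.

Optimisation is derivative-free Nelder-Mead from the zero vector, with an
explicit accept rule: if the search cannot improve on the identity, the
input is returned unchanged and flagged. The recovered coefficients need
not equal the simulated ones — on an annulus the radial powers are highly
collinear — but the cost reduction on a cupped noiseless phantom exceeds
99% and the downstream MBF RMSE drops by an order of magnitude, which is
the quantity that matters.

## Preprocessing

* **Aorta ROI.** Voxels are ranked by temporal enhancement range on lightly
  smoothed frames, thresholded at half the maximum, and grouped into
  connected components; components are scored by per-slice circularity and
  the most compact circular candidate wins (the aorta is smaller and
  rounder than the LV pool). The ROI mean TAC, referenced to its
  pre-contrast baseline, becomes the AIF.
* **Registration.** Translation-only, by phase correlation against the
  peak-enhancement frame, with the cross-power normalisation regularised so
  noise-only frequencies do not dominate. Translation is matched to the
  phantom's motion model and to the short, breath-held acquisitions this
  mirrors; deformable registration is out of scope. Integer shifts are
  recovered exactly; half-voxel motion is bounded by 0.5 voxel by
  construction.
* **Segmentation.** The interface is pluggable: externally produced masks
  (e.g. from a trained network) pass through after geometry validation, and
  a classical fallback covers phantom-like data — blood structures by
  thresholding the peak-enhancement frame, the myocardium as the
  mid-enhancement shell around the LV pool gated on time-averaged
  post-onset enhancement (averaging shrinks frame noise by $\sqrt{n}$).
* **Landmarks.** The LV centre is the blood-pool centroid on mid slices.
  The septal insertion points are found where an enhancing RV structure
  abuts the myocardium, modelling both cross-sections as circles and
  intersecting them, which gives sub-voxel insertion angles; without an RV
  structure the insertion angle must be supplied explicitly, and the
  pipeline raises an error rather than guessing.

## Polar maps and territory statistics

Myocardial MBF is displayed on an apex-centred bullseye: slice position
maps linearly to radius (apex at the centre) and the angle is measured from
the anterior septal insertion. The AHA-16 layout is used — basal and mid
rings of six 60° segments, an apical ring of four 90° segments rotated
45°, and *no apical cap*: segment 17 is excluded from MBF analysis
throughout. A segment is excluded when fewer than 30% of its geometric
polar-map pixels carry samples.

Territory summaries deliberately avoid single-segment minima: for each
coronary territory (right-dominant assignment) the representative MBF is
the lowest *mean of a spatially adjacent segment pair*, which damps
single-segment noise while preserving sensitivity to focal deficits. The
adjacency lists are generated from the segment geometry — two segments are
adjacent when their rings are the same or neighbouring and their closed
angular extents intersect (corner contact counts) — and the generated LAD
list is pinned by a data test to the ten canonical pairs
[1,2], [1,7], [1,8], [2,7], [2,8], [7,8], [13,14], [7,13], [8,13], [8,14];
RCA and LCX lists come from the same rule rather than being hand-typed.
Relative MBF divides each segment by the best territory representative.
Ischemia flags use strict `<` at the threshold, so a value exactly at the
threshold is *not* ischemic; the boundary convention is asserted in tests.

## Cohort statistics and the discordance classifier

* **CAD-RADS.** Percent stenosis bins to grades 0–5 ({0}, 1–24, 25–49,
  50–69, 70–99, {100}); fractional reads are truncated toward zero before
  binning. Grade ≥ 3 is obstructive.
* **Threshold derivation.** The operating MBF cutoff is derived by
  bootstrap ROC restricted to unequivocal territories (grades 0 and 4
  only; intermediate stenosis does not reliably determine flow). Each of
  1,000 replicates resamples rows — or whole patients, in the stratified
  variant — and maximises the Youden index over candidate thresholds at the
  midpoints of sorted unique MBF values, with "MBF below threshold" as the
  positive call. The Youden score is compared in integer arithmetic so
  exact ties resolve to the lowest (most sensitive) threshold. The
  reported threshold is the replicate mean; the CI is the percentile
  2.5–97.5 range. On the default two-normal generator the estimator is
  unbiased against the closed-form density-crossing optimum with a
  sampling standard deviation of about 5–6 mL·min⁻¹·(100 g)⁻¹ at
  500 + 500 territories, so individual draws occasionally sit near the
  ±10 acceptance band's edge — a property of the empirical-ROC estimator's
  slow (cube-root) convergence, not of the implementation.
* **Classification.** Per patient, rules fire in order: (1) any
  obstructive territory with territory MBF below threshold →
  `flow_limiting`; (2) all territories non-obstructive and > 50% of
  included AHA segments ischemic with global mean below threshold →
  `mvd_diffuse`; (3) all non-obstructive with ≥ 1 low territory →
  `mvd_focal`; (4) obstructive but all territories preserved →
  `discordant_preserved`; (5) otherwise `normal`. Giving flow-limiting
  precedence when both patterns coexist (e.g. a diabetic with obstructive
  disease) is this package's choice and is confined to one rule.
* **MVD truth recovery.** For cohort-level evaluation a patient is
  *predicted* MVD when the mean MBF of their non-obstructed territories is
  below threshold (falling back to all territories if every vessel is
  obstructed). Focal flow-limiting disease lowers flow only downstream of
  the stenosis, so preserved territories are exactly where diffuse MVD
  remains visible; using the classifier label alone would miscount MVD
  patients who also carry an obstructive lesion. With the default group
  separations this rule recovers the generator's MVD labels with
  sensitivity and specificity above 0.95.
* **Spearman / t-test.** Mid-rank Spearman with the t-approximation
  p-value, and the pooled-variance unpaired t-test (degenerate zero-variance
  input with equal means returns p = 1 by convention).

## The synthetic phantom: what it emulates, and what it does not

`build_phantom()` renders a short-axis left ventricle — an LV blood-pool
cylinder inside a myocardial annulus, a separate aortic cylinder, and an
optional RV stub for landmark work — with a conical apex-to-base taper
(15% radius reduction at the apex) matching ventricular geometry and
giving the volume through-plane structure. Myocardial sectors carry
configurable true (MBF, delay, k); blood structures carry a gamma-variate
AIF, the standard surrogate for a measured aortic input (peak enhancement
350 HU at 10 s with onset 4 s, α = 3, β = 2 s by default — values typical
of a 5 mL/s iodinated bolus at stress). Degradations are i.i.d. Gaussian HU
noise, the cupping artifact described above, and per-frame integer
translations (applied circularly and recorded). Default geometry is a
48×48×8 voxel grid at 2 mm spacing with 30 one-second frames, mirroring a
30 s dual-source stress acquisition; the fit-heavy simulations use a
24×24×4 variant with ~160 myocardial voxels so that paired
voxelwise-versus-superpixel comparisons over ten seeds stay cheap.

The cohort generator draws one row per (patient, vessel): per-vessel
CAD-RADS from a configurable distribution (defaults give ~17% obstructive
vessels and ~64% of patients with no obstructive vessel), territory MBF
from N(165, 61) for obstructive and N(274, 62) for non-obstructive
territories — the reported group separation for obstructed versus
non-obstructed territories after excluding diabetics — and diabetic
patients (17%) are diffusely MVD with probability 0.6, drawing *all*
territories from N(130, 35). The MVD mean/SD are our choice of a plausibly
"severely reduced, tight" global distribution consistent with diffuse
ischemia below a 200 threshold; they are stated here once and not tuned.

What passing these tests does **not** show about real data: the phantom
has crisp label boundaries (no partial volume), uncorrelated noise (real
CT noise is spatially correlated and object-dependent), translational
motion only, an artifact exactly inside the corrector's model family, and
an AIF sampled without beam-hardening in the aorta itself. Fallback
segmentation Dice scores near 1.0 on the phantom therefore say nothing
about clinical segmentation difficulty — the pluggable external-mask
interface exists precisely because clinical-grade segmentation is a
learned-model problem outside this package's scope.

## Numerical choices and degenerate inputs

* Curves must be finite with strictly increasing times; AIF resampling is
  linear with zero fill before the first sample and last-value hold after
  the acquired window (no extrapolation).
* TAC baselines subtract the mean of pre-contrast frames; onset is the
  first frame where the AIF exceeds 10% of its peak.
* An all-zero AIF, an empty myocardium mask, more clusters than voxels,
  all-excluded AHA reports, single-class ROC tables and constant Spearman
  inputs all raise immediate, specific errors rather than propagating NaN.
* All stochastic components (phantom noise, motion draws, cohort
  simulation, bootstrap) take explicit integer seeds; equal seeds give
  bit-identical outputs, and the pipeline manifest records the seed.

## Problem sizes

The test suite and acceptance script size their simulations to run
comfortably on one CPU: the recovery lattice is 336 fits, noise-robustness
runs 10 paired seeds on the ~160-voxel phantom (~1,600 voxelwise fits),
threshold recovery uses 500 + 500 territories with 1,000 bootstrap
replicates, the synthetic cohort has 700 patients (2,100 territories), and
the end-to-end discordance check runs four full pipeline executions on the
default phantom. These sizes are the package's chosen defaults for its own
validation; all are configurable upward.

## Known limitations

Single-input one-compartment kinetics (no RV/dual-input model, no
extraction-fraction estimation); translation-only registration; fixed
right-dominant territory assignment; polar maps use linear slice-to-radius
mapping rather than area-proportional; the 17-segment variant with an
apical-cap measurement is not implemented; the beam-hardening model is
simulation-matched rather than physics-derived; and the classifier's
precedence rule, while configurable in principle, is validated only in its
default order.
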