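# ccperf — quantitative dynamic cardiac CT perfusion

`ccperf` turns a dynamic contrast-enhanced cardiac CT acquisition into
quantitative myocardial blood flow (MBF, mL·min⁻¹·(100 g)⁻¹) and interprets
it against coronary CT angiography stenosis grades. Its purpose is the
clinical distinction that anatomy alone cannot make: a territory downstream
of an obstructive stenosis (CAD-RADS ≥ 3) with low MBF indicates
**flow-limiting disease**, while diffusely low MBF with clean epicardial
arteries indicates **microvascular disease (MVD)** — and obstructive
anatomy with preserved flow flags a **discordant**, possibly
hemodynamically insignificant lesion. The intended users are imaging
researchers building or validating perfusion pipelines.

## What it computes

The processing chain mirrors a clinical CCTP pipeline:

1. aorta ROI detection and arterial-input (AIF) extraction,
2. temporal registration (phase correlation, translation-only),
3. myocardium/aorta segmentation (pluggable external masks, classical fallback),
4. image-based automated beam-hardening correction,
5. kinetic-model MBF estimation with superpixel (SLIC) aggregation,
6. bullseye polar-map conversion,
7. AHA-16 segment report (apical cap excluded) with coronary-territory
   statistics and patient classification.

At its core is a one-compartment realisation of the simplified
Johnson-Wilson tissue model with three free parameters (flow, delay,
washout):

```
C_t(t) = f ∫₀ᵗ C_a(τ − Δ) e^{−k (t−τ)} dτ,   f = MBF / 6000 s⁻¹
```

fitted per superpixel by a coarse (Δ, k) grid with the flow solved in
closed form (the model is linear in MBF), then bounded refinement.
Territory MBF is the minimum adjacent-segment-pair mean within each
coronary territory; the operating threshold (200 mL·min⁻¹·(100 g)⁻¹ by
default) can be re-derived by bootstrap ROC / mean Youden index restricted
to unequivocal CAD-RADS 0 vs 4 territories.

Everything is validated on a built-in digital phantom (short-axis LV with
known per-sector kinetics, noise, motion and a cupping artifact) and a
synthetic per-territory cohort with known MVD labels — no patient data are
required anywhere.

## Worked example

Build a phantom with a perfusion deficit in the LAD territory (true MBF
150 vs 300 mL·min⁻¹·(100 g)⁻¹ elsewhere, 10 HU noise), run the full
pipeline, and classify against a CAD-RADS 4 LAD:

```r
library(ccperf)

cfg <- phantom_config(
  sector_truth = list(
    list(angle_deg = c(60, 180), slices = c(1L, 8L), mbf = 150, delay_s = 2, k_decay = 0.15),
    list(angle_deg = c(180, 60), slices = c(1L, 8L), mbf = 300, delay_s = 2, k_decay = 0.15)),
  noise_sd_hu = 10)
study <- build_phantom(cfg, seed = 11)
study
#> Dynamic CT study: 48x48x8 voxels x 30 frames, t = [0.0, 29.0] s, spacing 2x2x2 mm (with ground truth)

run <- run_pipeline(study, pipeline_config(septal_angle_deg = 120,
                                           cadrads = c(LAD = 4L, LCX = 0L, RCA = 0L)))
run
#> ccperf pipeline run
#>   aorta_roi    ok
#>   registration ok
#>   segmentation ok
#>   bhc          ok
#>   mbf          ok
#>   polar_map    ok
#>   aha_report   ok
#> territory representative MBF (mL/min/100g):
#>   LAD   RCA   LCX 
#> 146.8 300.8 287.7 
#> classification: flow_limiting
```

The LAD representative MBF (146.8) recovers the simulated deficit within a
few percent; the remote territories sit near their true 300; and because
the obstructive vessel matches the low-flow territory the patient is
classified `flow_limiting`. `render_polar_png(run$polar, 200, "polar.png")`
writes the bullseye with the threshold annotated on the colour bar.

Deriving the MBF threshold from a synthetic cohort:

```r
tab <- simulate_cohort(cohort_config(n_patients = 700, seed = 3))
bootstrap_youden_threshold(tab, n_boot = 1000, seed = 1)
#> Optimal MBF threshold: 220.9 mL/min/100g (95% CI 202.0-243.5), 1000 bootstraps
```

With the default generator separations (obstructed territories
N(165, 61), non-obstructed N(274, 62)) the bootstrap-mean Youden threshold
lands near the analytic density-crossing optimum (~220).

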