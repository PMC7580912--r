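# octaquant

Quantification of retinal capillary perfusion from en-face optical coherence
tomography angiography (OCTA).

## The problem

OCTA renders retinal blood flow as en-face decorrelation maps of the
superficial (SCP), middle (MCP) and deep (DCP) capillary plexuses.  Turning
those maps into perfusion numbers requires a binarization threshold that
separates true vessel signal from background noise, and the choice of
threshold dominates every downstream metric.  Generic auto-thresholders
(Mean, Huang) tend to over-estimate vessel density precisely where it
matters most — eyes with severe capillary dropout — because they rebalance
the cutoff against an emptier image.

`octaquant` implements a *vessel-length-based* threshold derived from the
DCP, the plexus most sensitive to the threshold choice.  For each candidate
threshold *t* the DCP slab is binarized at *t*, skeletonized (every vessel
reduced to a 1-pixel centreline), and the skeleton pixel count *L(t)*
recorded.  Noise decays faster than vessel signal as *t* rises, so *L(t)*
falls steeply through the noise range and plateaus over the signal range.
Ordinary least squares lines are fitted to the steep (noise) and plateau
(signal) portions of the declining limb — the breakpoint is chosen by
exhaustive two-segment SSE minimization — and the threshold is the
intersection of the two lines:

    t* = (c_signal − c_noise) / (m_noise − m_signal)

rounded to the nearest integer.  The single DCP-derived *t\** binarizes all
plexus slabs of that eye, and the per-eye metrics follow, evaluated inside
the parafoveal annulus (outer diameter 3 mm, inner 1 mm):

* **VD** — vessel density, % of the annulus covered by binarized vessels;
* **VLD** — vessel length density, skeleton length per unit area (mm⁻¹);
* **AFI** — adjusted flow index, mean normalized decorrelation of
  suprathreshold pixels;
* **FAZ** — foveal avascular zone area (mm²), from a traced mask or an
  assisted flood fill of the full-retina slab.

The cohort layer reproduces the staging statistics used with such data:
Spearman trends across the ordered severity stages (0 = healthy, 1 =
diabetes without retinopathy, 2–4 = mild/moderate/severe non-proliferative
diabetic retinopathy), ANCOVA adjusted for age and scan quality (Q-score)
with Benjamini–Hochberg pairwise post-hoc contrasts, Cohen's *d*,
noncentral-*t* a-priori sample sizes, and ROC screening analysis
(severe vs mild+moderate NPDR).

A seeded synthetic generator produces multi-plexus angiograms with ground
truth (vessel masks, centrelines, true VD/VLD, noise/signal boundary) and
cohort tables with stage effects and covariate confounding, so the whole
pipeline is testable without patient data.

## Worked example

```r
library(octaquant)

# one synthetic eye: four slabs + ground truth
eye <- generate_angiogram(synthetic_spec(rng_seed = 42))
res <- run_eye(eye$images, octa_config(), eye_id = "demo")
res$threshold_result
#> <threshold_result> threshold = 58 (intersection 57.89, breakpoint 54, ...)
res$metrics
#> <metric_set> threshold = 58
#>   VD (%):   SCP 49.37, MCP 43.93, DCP 43.86
#>   VLD (/mm): SCP 22.89
#>   AFI:      SCP 0.745, MCP 0.745, DCP 0.745
#>   FAZ (mm^2): 0.216
eye$truth$DCP$true_vd_pct   # generator truth: 43.86 — recovered exactly
```

The generator's noise support ends at intensity 55 and its vessel support
starts at 150, so a correct threshold lies in (55, 150]; the method lands at
58, just above the noise ceiling, and the measured DCP vessel density
matches the generator's ground truth.

```r
# synthetic five-stage cohort and the staging statistics
tab <- generate_cohort(cohort_spec(rng_seed = 42))
rep <- run_cohort_report(tab, c("SCP_VD", "MCP_VD", "SCP_VLD"))
rep$spearman
#>   parameter    rho  p_value
#> 1    SCP_VD -0.667 4.57e-15     # perfusion falls with severity
#> 2    MCP_VD -0.610 3.16e-12
#> 3   SCP_VLD -0.700 5.23e-17
rep$ancova
#>   parameter     0     1     2     3     4 overall_p
#> 1    SCP_VD 45.90 43.84 39.05 38.91 35.76 1.77e-09  # adjusted means/stage
#> ...
rep$roc
#>   parameter   auc sensitivity specificity operating_threshold
#> 1    SCP_VD 0.698       0.778       0.667                36.7
#> ...
```

The adjusted means are per-stage model predictions with age and Q-score at
their sample means; the ROC rows quantify how well each parameter flags
severe NPDR among mild–severe eyes (positive call when the value falls at or
below the operating threshold).

A command-line front end ships in `inst/cli/octaquant`
(`threshold`, `metrics`, `simulate-eye`, `simulate-cohort`, `stats`,
`run-study`).

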