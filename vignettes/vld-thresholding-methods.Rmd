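---
title: "Vessel-length-based thresholding and perfusion statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-length-based thresholding and perfusion statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octaquant)
```

# The model

En-face OCTA slabs are decorrelation maps: each pixel's intensity reflects
signal variation between repeated B-scans, high over moving blood, low over
static tissue.  The working model of this package is a two-population
mixture — a background noise distribution occupying the low end of the
intensity range and a vessel signal distribution at the high end — plus the
geometric prior that true vessels are connected curvilinear structures
while noise is spatially incoherent speckle.

The thresholding algorithm exploits the interaction of those two facts with
skeletonization.  Let $L(t)$ be the number of skeleton pixels after
binarizing the deep-plexus slab at threshold $t$ (foreground where
intensity $\ge t$) and thinning every structure to unit width.  Speckle
produces many small fragments, each contributing skeleton pixels, so as $t$
sweeps up through the noise range $L(t)$ collapses steeply; once only
vessels remain, $L(t)$ is nearly flat, because removing sub-threshold
pixels from a vessel's *edges* does not shorten its centreline.  The
transition between regimes estimates the noise/signal boundary.  Two
ordinary-least-squares lines are fitted to the steep and plateau portions,
and the threshold is the (rounded) abscissa of their intersection.  One
threshold per eye, computed from the DCP, binarizes all plexuses, keeping
the layers mutually comparable.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `fov_mm` | 3.0 | mm | physical field width; sets the pixel pitch `fov_mm / width` (≈9.9 µm at 304 px) |
| `t_min`, `t_max` | 1, `2^bit_depth − 2` | intensity | sweep bounds; unit step — the finest grid the data supports |
| `min_segment` | 10 | points | minimum sweep points per fitted segment; guards against fitting a "segment" to noise |
| `fit_upper_frac` | 0.9 | — | upper fit-window bound as a fraction of the intensity maximum, excluding the extreme-threshold falloff |
| `rise_tol` | 0.05 | — | fraction of the limb's drop by which counts may climb above the running minimum before the window is cut (see below) |
| annulus | 3 mm / 1 mm | mm | parafoveal analysis ring; half-open membership so concentric rings tile |
| `closing_radius_px` | 2 | px | morphological closing before the assisted FAZ flood fill |
| `fdr` | 0.05 | — | Benjamini–Hochberg level for post-hoc flags |

# Numerical choices

**Fit-window delimitation.** The source method fits "only the linear
regions" of the steep and plateau portions, a delimitation originally done
by eye.  This package operationalizes it deterministically: the window
starts at the global argmax of $L(t)$ (below it the image saturates toward
all-foreground, whose skeleton is degenerate) and ends at the *earliest* of
(i) `fit_upper_frac` times the intensity maximum and (ii) the point where
the curve stops declining — three consecutive counts exceeding the running
minimum by more than `rise_tol` of the drop so far (with a floor of three
robust noise SDs, estimated from first differences, so ordinary curve noise
never truncates the fit).  Rule (ii) matters on data whose vessel
intensities have a bounded support: above the vessel minimum the vessels
themselves fragment and the skeleton count *rises* again, a regime that is
neither noise limb nor signal plateau.

**Breakpoint and intersection.** Every admissible breakpoint (≥
`min_segment` points per side) is scored by total SSE of the two
independent OLS fits; ties resolve to the smallest breakpoint, which can
sit one grid unit below the geometric knee when the crossing lies exactly
on a data point (the knee point then fits either segment).  Near-parallel
segments (relative slope difference below 1e−8) raise a degenerate-fit
error rather than returning an explosive intersection; an intersection
outside the fitted range raises a fit-invalid error.  The final threshold
rounds half away from zero and clamps to the sweep bounds with a warning.

**Binarization and skeleton.** Foreground is `intensity >= t` (the source
does not state ≥ vs >; ≥ makes the constant-image boundary case
unambiguous).  Skeletonization is sequential topology-preserving thinning:
simple, non-endpoint border pixels are deleted in four directional
subpasses (north, south, east, west) until stable, using the 8-neighbour
crossing number as the simplicity test.  Sequential deletion makes
topology preservation unconditional — parallel Zhang–Suen can erase a 2×2
object outright.  Thick crossing points can lock locally (every member of
a 2×2 block has two neighbour runs that reconnect just outside the 3×3
window); a cleanup pass resolves these with a bounded-window connectivity
check that deletes a block member only if its neighbours remain mutually
connected within a 10-pixel window.  The skeleton contract — subset of the
input, no fully-foreground 2×2 block, 8-component count preserved — is
enforced by tests, not assumed.  Exact pixel-for-pixel agreement with any
particular ImageJ plugin is a non-goal.

**Metrics.** VLD counts skeleton pixels times the pixel pitch (matching
pixel-count practice; an optional flag weights diagonal links by √2).  AFI
averages *normalized* intensities over pixels `>= t` using the same
DCP-derived threshold — the source never states a separate AFI threshold,
and one shared cutoff is the reading most consistent with "all layers
binarized to the same threshold".  The FAZ is taken from a traced mask when
given; the assisted mode (closing + 4-connected flood fill from a seed)
replaces manual-tracing ergonomics and refuses fills that escape to the
image border or exceed 2 mm².

**ANCOVA machinery.** The model is `value ~ stage + age + q_score`;
adjusted means are predictions at the whole-sample covariate means, the
overall p comes from the stage-term F-test, and pairwise contrasts use the
model's pooled residual variance (deterministic, and the standard reading
of "post-hoc after a significant ANCOVA").  Covariates with zero variance
are dropped, which also makes the two-group no-covariate case collapse
exactly onto the pooled t-test.  The BH family is the 10 pairwise
comparisons of one parameter, not the union across parameters.  The ROC
operating point maximizes Youden's J with ties broken toward sensitivity,
matching a screening use-case; the default contrast is severe NPDR versus
mild+moderate.  Sample sizes use exact noncentral-t power, incremented
from n = 2.

# The synthetic world

`generate_angiogram()` emulates exactly the structure the threshold method
relies on, and no more:

* branched curvilinear capillary networks, grown by biased random walkers
  with stochastic branching (a few wide arteriole-like vessels in the SCP
  only, where skeletonization is meant to cancel their influence);
* a central avascular disk (radius 0.25 mm ≈ 0.2 mm², the healthy-eye
  scale);
* bimodal intensities — background uniform on [20, 55], vessels uniform on
  [150, 230] on the 8-bit scale by default, i.e. cleanly disjoint supports
  whose true boundary (55) is recorded in the ground truth;
* severity as a `dropout_fraction` dial deleting whole branch segments
  before rendering (ground truth reflects the post-dropout network);
* a full-retina slab as the union of the three plexus networks.

The step budget scales with pixel area (0.32 steps/px) so smaller test
images have comparable vessel density; walker counts, branch probability
(0.05/step) and widths (1–3 px capillaries at ≈10 µm/px) were chosen once
for visual and densitometric plausibility (healthy parafoveal VD in the
40s of percent) and are not tuned against tests.  All randomness flows from
one seed through per-plexus, per-phase L'Ecuyer-CMRG substreams, so adding
draws to one phase perturbs nothing else and any plexus can be regenerated
alone, bit-identically.

What the generator does **not** model: OCT speckle statistics, projection
artifacts and decorrelation tails, depth-dependent signal attenuation,
motion artifacts, vessel-diameter distributions, or any hemodynamics.  A
green threshold-recovery test therefore establishes that the algorithm
finds the noise/signal boundary of a clean bimodal angiogram-like image —
not that it is robust to every artifact of clinical data.  Conversely AFI
on synthetic eyes sits near 0.75 (the mean of the vessel support), not in
the clinical 0.41–0.45 range; AFI tests check the estimator, not the
physiology.  Synthetic cohort tables draw parameters from per-stage
normals (defaults approximating published covariate-adjusted summaries)
with optional linear age/Q-score effects applied around reference values
of 52 years and Q = 8, giving genuinely confounded cohorts for exercising
the adjustment.

# Degenerate inputs and edge cases

Constant images have no Huang threshold (error) and a VLD curve that drops
to zero immediately above the constant.  Masks must be non-empty for VD/VLD
(error otherwise); AFI with no suprathreshold pixel is undefined (error)
rather than 0, which would fake a flow measurement.  An annulus partially
clipped by the image is a geometry error, but an outer disk that swallows
the whole field is accepted as the degenerate full-field region.  Per-eye
failures inside a study never abort the cohort: the report covers completed
eyes and failures are first-class rows.

# Known limitations

* PNG/TIFF support is a minimal internal codec (no raster package exists in
  the target environment): non-interlaced grayscale PNG and uncompressed
  single-sample TIFF only.
* The fit-window rules, while deterministic, are this package's
  operationalization of a visually-delimited procedure; cohort mean
  thresholds in the mid-50s on 8-bit data are a plausibility anchor, not a
  validation.
* The skeleton cleanup's bounded-window check is sufficient but not
  necessary: a pathological crossing whose arms reconnect only beyond 10
  pixels would retain a 2×2 block rather than risk splitting a component.
* Sequential thinning's skeleton position depends on pass order; only
  skeleton-level properties (length, topology) are contractual.
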