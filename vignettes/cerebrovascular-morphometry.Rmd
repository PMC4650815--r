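---
title: "Quantifying mouse cerebrovascular morphology from micro-CT angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mouse cerebrovascular morphology from micro-CT angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomorph)
```

## The measurement problem

Contrast-enhanced micro-CT with a long-circulating blood-pool iodine agent
can resolve the complete cerebral arterial tree of a live mouse down to
vessels of roughly 40 µm diameter at 19 µm isotropic voxels. Turning such a
Hounsfield-unit (HU) calibrated volume into biology-grade numbers — vessel
diameters, tortuosity, the width of the Circle of Willis, counts of small
perforating branches, a visibility grade — requires a chain of image
operations whose errors are hard to audit on animal data, because no ground
truth exists there. This package implements the full measurement chain
*and* a synthetic phantom generator that emulates the acquisition physics,
so every stage can be validated as parameter recovery against known truth.

The pipeline is

1. **phantom / volume** — a parametric vessel network rasterized into a
   binary mask and rendered into a noisy HU volume
   (`make_cow_phantom()`, `rasterize()`, `render_ct()`);
2. **enhancement** — multiscale Hessian vesselness (Frangi-type) and
   hysteresis segmentation (`frangi_vesselness()`, `segment_vessels()`);
3. **skeleton** — topology-preserving 3D thinning and centerline graph
   extraction (`skeletonize()`, `build_graph()`, `prune_spurs()`,
   `match_labels()`);
4. **morphometry** — diameters, arc:chord ratio, middle curvature,
   Circle-of-Willis width, branch counts, visibility
   (`segment_diameter()`, `cow_width()`, `count_branches()`, ...);
5. **statistics** — a normality-gated two-group comparison
   (`compare_groups()`, `run_cohort_analysis()`).

## The acquisition model

Three acquisition knobs drive the phantom renderer, each with the
dependence a micro-CT physicist would expect:

* **Scan geometry.** The geometric magnification is the ratio of
  source-to-detector to source-to-rotation-center distance; the bundled
  presets are the published high-resolution (309.90 mm / 98.43 mm,
  magnification 3.15, 19 µm voxels) and low-resolution
  (312.93 mm / 183.93 mm, 1.70, 35 µm) configurations. A 19 µm voxel holds
  ~6.9×10⁻⁶ µL of tissue, which is why photon starvation dominates at high
  resolution.
* **Radiation dose** scales linearly with the number of projections
  (`scale_dose()`): a 180-projection calibration measurement scales by 2,
  4 and 8 to the 360/720/1440-projection protocols.
* **Noise** follows the inverse-square-root of total photon flux
  (projections × exposure × current), anchored at the reference protocol
  (1440 projections, 850 ms, 0.5 mA): quartering the projection count
  doubles the reconstructed noise (`noise_sigma()`).
* **Contrast.** Vascular enhancement is linear in injected iodine dose:
  `vessel HU = background HU + slope × dose`. The background (parenchyma)
  HU presets per dose/kVp combination are the measured values (51 HU at
  1.1 g I/kg and 50 kVp; −87 at 1.1/70; 73 at 2.2/50; −20 at 2.2/70). The
  slope defaults to 300 HU per (g I/kg); this is a package calibration
  constant — the source study plots, but does not print, vascular HU — and
  it is exposed in the contrast model. kVp dependence beyond the
  background presets is deliberately not modeled (measured in the study,
  but no law was reported).
* `sigma_ref = 60` HU at the reference protocol is the second calibration
  constant, chosen so that a 40 µm vessel sits near the visibility floor
  at 360 projections, reproducing the qualitative projection-number effect
  on small-vessel conspicuity. Both constants are configurable; no
  acceptance check depends on their absolute values, only on orderings.

## What the phantom generator emulates — and what it does not

`make_cow_phantom()` builds a planar elliptical ring of six labeled arcs
(anterior left/right, lateral internal-carotid analogs, posterior
left/right) plus two afferent trunks (azygos-pericallosal and basilar
analogs). The ring's lateral extremal separation *is* the ground-truth
Circle-of-Willis width, and it is preserved exactly under the
`straightening` deformation (arcs are blended toward their chords, then
the lateral extent is rescaled). Focal stenoses are Gaussian dips in the
radius profile. `make_branching_trunk()` reproduces the branch-counting
setup: side branches originating from a window of trunk arclength.

Rasterization uses 3× supersampling with a 50% occupancy rule, so
partial-volume behavior near the voxel size is faithful: a 40 µm vessel
survives at 19 µm voxels and disappears at 35 µm, as in the real
acquisition. Rendering applies a Gaussian point-spread function of
FWHM 1.5 voxels (the scanner's effective resolution is near the voxel
size) and additive Gaussian noise from the flux law; an optional
concentric-ring artifact (radial sinusoid) is available.

The generator does **not** attempt mouse anatomy: no skull-base geometry,
no flow, no beam hardening, no projection-space reconstruction. A green
test therefore establishes that the *measurement chain* is accurate on
vessels of realistic size, contrast and noise — not that the pipeline
segments real mouse angiograms without parameter adjustment.

## Numerical choices that matter

* **Vesselness.** Gaussian-derivative Hessians with γ = 1 scale
  normalization (second derivatives × σ²); eigenvalues sorted by absolute
  value; bright-polarity gate (λ₂, λ₃ < 0); α = β = 0.5; the structureness
  weight `c` defaults to half the per-scale maximum Frobenius norm
  ("auto"). Derivative kernels are moment-corrected so constant volumes
  give exactly zero response and an additive HU offset cannot change the
  output. The default scale ladder is 6 geometric scales from 15 to
  150 µm, covering 40–300 µm vessel diameters (the tubular optimum sits
  near σ = radius/√2). The original analysis used an ImageJ Frangi plugin
  with unstated parameters; no test depends on matching it bit-for-bit.
* **Segmentation** is hysteresis thresholding (seeds ≥ high, grown over
  ≥ low, 26-connected), preserving thin low-contrast vessel tails.
* **Skeletonization** is sequential border thinning over six directional
  subcycles, deleting only *simple points* in the Malandain–Bertrand sense
  (one 26-connected foreground component in the neighborhood, one
  6-connected background component touching the voxel), so connected
  components and loops are preserved exactly. Two guards shape the result:
  voxels already part of a one-voxel-thick curve (≤ 2 neighbors) are
  frozen — this keeps closed loops from contracting homotopically and
  branch tips from eroding — and a final pass dissolves redundant corner
  voxels, which removes frozen 3-voxel micro-triangles. Consequences: a
  ring mask keeps exactly one cycle; free tube ends retain their length to
  within about one tube radius; rings smaller than a few voxels would
  collapse.
* **Graphs.** Skeleton voxels with ≠ 2 neighbors become nodes; adjacent
  node voxels are condensed into one node at their centroid; pure cycles
  get one artificial node at the lexicographically smallest voxel. Spur
  pruning removes terminal edges shorter than 3 voxels by default and
  merges pass-through nodes; cycles are never pruned.
* **Label transfer.** Each detected polyline point takes the nearest
  ground-truth segment; edges are split at label-run boundaries and a run
  keeps its label only if its mean distance is below 2 voxels. (Splitting
  is needed because truth label boundaries — e.g. the arc boundaries of
  the ring — need not be branch points of the detected graph.) In the
  original workflow target vessels were selected manually; this automated
  matcher is a documented stand-in, not a claim about that workflow.
* **Diameter** is the median over interior centerline points of the
  *minimum* chord over 90 ray-pair directions in the plane orthogonal to
  the local tangent, with the mask boundary interpolated at the trilinear
  0.5 level. The minimal statistic matches the stated "minimal radial
  lengths" rule and is robust to oblique sections; the median makes the
  segment value robust to focal stenoses. Tangents come from central
  differences on a 5-point moving average. Binary-mask digitization
  biases the minimum slightly low (about half a voxel on large tubes),
  well inside the one-voxel recovery target.
* **Middle curvature** is the Menger curvature (inverse circumradius) of
  the arclength midpoint and the two points ±0.25 mm along the
  centerline. The source's exact construction lives in supplementary
  material that is not available; the Menger construction is this
  package's documented substitute, validated against analytic arcs.
* **Circle-of-Willis width**: the anterior origin is the junction of the
  two anterior arcs (by analogy, where the internal carotids meet the
  azygos pericallosal artery); the anterior–posterior axis runs through it
  toward the posterior junction; the width is the maximum over axis
  positions of the left–right lateral separation measured orthogonal to
  the axis. When noise fragments a junction node the origin falls back to
  the midpoint of the closest endpoint pair of the two anterior arcs. The
  exact published construction is likewise in unavailable supplementary
  material; all width acceptance is against generator ground truth.
* **Visibility** is a computable surrogate for the human 4-point scale
  (absent/weak/good/very good): the mean contrast-to-noise ratio along
  the true centerline, cut at CNR 1 / 3 / 6. The cut points are
  calibration constants; only orderings across protocols are asserted.
  SNR subtracts the background mean (contrast-to-noise convention) because
  parenchyma HU varies strongly with kVp; the unsubtracted variant is a
  flag away.

## The gated statistical comparison

Group comparisons follow the stated procedure exactly: a Kolmogorov–
Smirnov test of each sample against a normal with that sample's mean and
SD gates, at α = 0.05, between a two-sided t-test (Welch by default;
pooled is a flag) and a two-sided Wilcoxon rank-sum test (exact for
small tie-free samples). Testing against a *fitted* normal is known to
inflate KS p-values (the Lilliefors effect), making the gate permissive
toward the t-branch; the procedure is kept as stated rather than silently
substituting the Lilliefors correction, and the caveat is recorded here.
No multiple-testing correction is applied by default, matching
per-comparison reporting; a Holm option exists. Monte-Carlo calibration
(`type1_power_table()`) confirms type-I error near the nominal 5% under
normal and heavy-tailed nulls.

A note on the headline parameter-recovery experiment: with the published
group parameters — widths Normal(2.82, 0.19) for 7 wild-type analogs vs
Normal(2.56, 0.08) for 6 knock-out analogs — the gated two-sided
comparison at α = 0.05 has a true rejection rate of about 0.82 (direct
simulation, 20 000 replicates; 0.81 for the pooled t variant, 0.74 for
an always-Wilcoxon variant), before any measurement error. A single
cohort will usually, but not always, reach p < 0.05 — consistent with a
single reported significant comparison, but a 90% reproduction rate is
not attainable from these group parameters, and the acceptance suite
reports that honestly rather than adjusting the generator.

## Scaling decisions in the test suite

The heavy acceptance checks are scaled to a single CPU: the
200-replicate power study measures each subject through the geometric
chain (rasterize → skeletonize → graph → label → width) on a reduced
field of view at 19 µm, while rendering noise and the vesselness stages
are validated on one complete 7-vs-6 cohort through the full imaging
chain (all widths within 2 voxels of truth). The bundled `acta2-demo`
pipeline configuration runs the complete imaging chain at 35 µm with 3
subjects per group in about a minute.

## Known limitations

* Skeleton branch tips recede by up to one tube radius; arclength-based
  quantities near free vessel ends inherit that bias (the branch-count
  window measures from a junction, which is unaffected).
* Diameters below ~2 voxels are reported from a binarized mask and are
  biased low by partial volume; the recovery guarantee is one voxel.
* The renderer's noise is white Gaussian in HU; real filtered
  back-projection noise is spatially correlated, so absolute CNR values
  are optimistic and only orderings are trusted.
* Anisotropic volumes are rejected rather than resampled.
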