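---
title: "Methods: 3D joint-space morphometry on HR-pQCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D joint-space morphometry on HR-pQCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jswmorph)
```

## The measurement problem

Hereditary hemochromatosis arthropathy narrows the joint spaces of the second
to fourth metacarpophalangeal (MCP) joints, often to a fraction of a
millimetre, and deforms them asymmetrically (hook-like osteophytes at the
metacarpal heads, localized bone-on-bone contact). HR-pQCT images these
joints in vivo at an isotropic voxel size of 0.082 mm over a stack of up to
330 slices, with an effective spatial resolution of about 0.130 mm — fine
enough that joint spaces a single voxel wide are still measurable. This
package implements the full analysis chain from such a volume to the six
joint-space parameters (JSV, JSW, JSW.SD, JSW.MIN, JSW.MAX, JSW.AS), the
cohort-level quality-control and statistics machinery around it, and a
synthetic phantom generator that provides analytic ground truth in place of
patient data, which are not publicly deposited.

## Pipeline

Per joint, the stage order is fixed:

1. **Bone segmentation** (`segment_bone`): global thresholding, either a
   calibrated fixed threshold or Otsu's method on a 256-bin histogram. Otsu
   is the default because scanner-specific calibration chains are not
   reproducible without the scanner; for noiseless synthetic volumes the
   intensity midpoint is exact. When the two modes of a histogram are
   separated by empty bins, the between-class variance has a plateau; we take
   its midpoint, so the threshold sits centrally in the valley.
2. **Bone splitting** (`split_joint_bones`): 26-connected components;
   components below 1% of the bone volume are discarded (this implements the
   exclusion of adjacent sesamoid-like bodies deterministically). Two major
   components are labelled by position along the joint axis (the distal-most
   becomes the metacarpal); a single bridged component — the signature of
   direct bony contact — is flagged `needs_manual`. The operator's short
   semi-automatic contouring step is replaced by `apply_manual_split`, which
   assigns bone voxels inside a supplied coarse contour to the distal bone.
   This preserves the two-path (automatic / manual) workflow and its
   bookkeeping without an interactive operator.
3. **Periosteal filling** (`periosteal_mask`): morphological closing with a
   Euclidean ball (default radius 5 voxels) followed by 6-connected hole
   filling, so trabecular voids and cysts become part of the solid periosteal
   mask. The operation is extensive and idempotent; the outer surface moves
   by at most the closing radius.
4. **Joint-space mask** (`build_joint_space_mask`): morphological closing of
   the union of both periosteal masks with a bridging ball (default radius
   2.5 mm — larger than any anatomical MCP gap, so the closing always bridges
   the joint), minus the bones, keeping components adjacent to both bones,
   and finally restricted to voxels that have distal bone on one side and
   proximal bone on the other along the joint axis. The lateral extent of a
   joint space has no canonical definition; the bridging radius is an exposed
   parameter and is recorded in every run manifest. Bones in contact with no
   remaining space voxel yield an empty mask with the ankylosis signal.
5. **JSW map** (`compute_jsw_map`) and **summary**
   (`summarize_morphometry`), described next.
6. **Quality control** (`apply_inclusion_rules`, `check_joint_coverage`,
   `tally_success_rates`), described below.

All tunable parameters live in one `pipeline_config()`; runs are
deterministic given config and inputs, and every output directory carries a
manifest naming the hash of the canonical YAML form of the config.

## The local width map: discrete semantics

The width at a joint-space voxel is the diameter of the largest sphere that
fits between the bone surfaces and covers the voxel (maximal-inscribed-sphere
local thickness, the standard model-independent thickness definition in bone
morphometry). Three discrete choices pin the semantics exactly:

- **Boundary model.** The bone/space interface is sampled as the discrete
  0.5-isosurface of the binary field: a half-voxel-grid point is a boundary
  sample when at least half of the voxels containing it are background.
  Out-of-grid voxels count as continuation of the volume, never as
  background, so a gap running to the grid border is not artificially capped
  there. Two simpler models fail: treating background voxels as solid cubes
  lets infinitesimal staircase corners clip the spheres, and curved gaps then
  read about 1.3 voxels low; treating them as inscribed balls lets spheres
  leak diagonally between them, and a one-voxel slab then reads 1.45 voxels.
  The isosurface model keeps slabs of every integer thickness exact and
  measures curved shells to within 0.2 voxels in the mean.
- **Sphere centres** are sampled on the half-voxel grid. For even-thickness
  slabs the optimal centre is a mid-plane point between voxel layers, which
  the half grid contains; this is what makes slabs exact at both parities.
- **Coverage.** A sphere covers a voxel when it intersects the voxel's cube
  (per-axis clamped offsets), not merely its centre. Voxels at the very skin
  of the gap sit on the rim of their best covering sphere; requiring
  centre-coverage makes their value collapse under centre rounding, while
  cube-intersection coverage is robust and still bounded by the true gap
  plus one voxel.

On the doubled grid (half-grid points at integer coordinates, voxel centres
at odd triples) the squared radius is an integer (exact squared Euclidean
distance transform, computed with the lower-envelope algorithm), and the
coverage test is integer arithmetic, so implementation and oracle can be
compared voxel for voxel. The brute-force oracle (`local_thickness_oracle`)
enumerates every boundary sample and every candidate centre directly and
shares no code with the transform-and-paint fast path beyond the definition
of a boundary sample.

**Where spheres live.** The spheres are bounded by bone only: the structure
for the distance transform is the full non-bone space, not the joint-space
mask. Measuring the mask itself would let its artificial lateral cut pinch
the spheres (near the cut, widths would read a fraction of the true gap).
Sphere centres are restricted to non-bone voxels within half the bridging
radius of the joint-space mask: a sphere covering a mask voxel is centred
within about half the local width of it, so this bound loses nothing, while
it excludes distant free-space spheres, which cannot see joint-space voxels
past the interposed bone and would only cost time. With centre domain equal
to the structure the computation reduces to the plain local-thickness
transform, which is the form the oracle-equivalence tests pin down.

**Summary conventions.** JSV is the exact voxel count times the voxel volume
(integer arithmetic on counts). JSW.SD is the population (divide-by-N) SD of
the map — a descriptive summary of a fully observed field, not a sample
estimate. JSW.MIN is the absolute minimum by default; published minimal
widths go down to a single voxel, implying no trimming. A robust variant
(drop the lowest 0.1% of map voxels) is available but off by default. When
segmentation detected bony contact, or the joint space is empty, the joint is
flagged ankylotic, JSW.AS is undefined (`NA`) and downstream statistics
exclude the joint.

## Synthetic phantoms

`make_phantom` voxelizes analytic two-bone solids by centre sampling (a voxel
is bone iff its centre lies in the solid), renders bone at intensity 1 on
background 0, then optionally applies Gaussian blur (FWHM default 0.130 mm,
matching the scanner's effective resolution) and additive Gaussian noise with
a configurable SD (no noise magnitude is published for HR-pQCT grayscale
data, so the default is 0 and tests that need noise state their own value,
0.03–0.05, at which Otsu segmentation recovers the truth with Dice above
0.95). Noise is drawn under the seed carried in the phantom specification,
so identical specifications give
bit-identical volumes.

- **Plates** span the full lateral grid cross-section. The gap is anchored at
  a voxel plane, so a gap of *g* mm discretizes to exactly `round(g/h)`
  one-voxel layers; integer-voxel gaps are measured exactly, and the
  joint-space mask of facing plates is exactly the gap block (no lateral
  background exists to erode its rim).
- **Ball-and-cup** joints articulate a convex head (sphere of radius R_h on a
  supporting shaft that intentionally runs out of the bottom of the stack,
  like a metacarpal shaft) with a concave hemispherical cup (cavity radius
  R_c > R_h). Offsetting the cavity centre towards the head by d gives the
  analytic gap field g(θ) = R_c − sqrt(R_h² + d² + 2 R_h d cos θ) over the
  polar cap: minimum R_c − R_h − d at the pole, maximum at the rim. (A
  physical cup cannot produce a gap maximum of R_c − R_h + d: that would
  require the cavity to wrap the full sphere, leaving no aperture for the
  shaft.)
- **Contact patches** bridge a stated fraction of the articulating area with
  bone (a central disc for plates, a polar cap for ball-and-cup), setting the
  ground-truth contact flag; fraction 1 produces a fully ankylotic single
  body. **Osteophytes** are cone-shaped outgrowths at the head rim, tilted
  toward the opposing bone; they invalidate the analytic gap extrema (set to
  `NA`) since the intrusion is not described by the closed-form field.

What the phantoms do *not* emulate: trabecular microarchitecture (bones are
solid), beam hardening and reconstruction kernels, and motion artifacts —
motion exists only as the 1–5 quality grade consumed by quality control.
Passing phantom tests therefore validates the geometry and the measurement
chain, not robustness to scanner physics.

`synthesize_cohort` draws per-subject, per-joint parameter values
independently from the configured group means and SDs, truncated below at
zero by rejection. Independence across joints is a deliberate simplification
(no within-subject covariance is published). The zero truncation matters:
for parameters whose mean is less than about 2.5 SDs above zero (JSW.MIN in
some groups, and all JSW.AS groups, whose published SDs rival their means),
the truncated mean exceeds the configured mean by well over 1%, so
mean-recovery checks are only meaningful where the analytic truncation shift
is negligible; the recovery tests compute that shift
(mean + sd·φ(mean/sd)/Φ(mean/sd)) and check every parameter with shift below
0.5%. The reference table `hh_reference_params()` carries the published group
statistics (16 HH men, 8 HH women, MCP 2–4; the matched subanalyses of 8
women and 5 men per arm, MCP 2–3) and is the generator input as well as the
source of the percent contrasts.

## Quality control

The study's inclusion rules are: motion grade 4–5 excluded (the 1–5 grade is
visual metadata, not computed from image content), joints whose articulating
surfaces are not fully contained in the slice stack excluded, ankylotic
joints excluded. Reasons are logged with fixed precedence motion → coverage →
ankylosis, and inclusion is order-independent. Articulating surfaces are
defined as bone voxels adjacent to the joint-space mask, so a shaft running
out of the stack does not fail the coverage check while a joint surface cut
by the stack does. Segmentation success tallies report, per joint and
overall, the percentage (one decimal) of automatic first-attempt successes
and of joints needing manual intervention over the included records; the
denominator question (whether the ankylotic joint is removed before or after
grading) is resolved by tallying whatever record set the caller passes, so
both denominators are one call away.

## Statistics

`compare_groups` reproduces the study's routing: Shapiro–Wilk on both groups
(paired: on the differences) at α = 0.05 — the routing gate is not published,
so the global significance level is used; normal data take Student's t
(paired t), otherwise Mann–Whitney U (Wilcoxon signed-rank). The
Mann–Whitney p is exact when there are no ties and the smaller group has at
most 8 observations, otherwise the mid-rank normal approximation without
continuity correction; both behaviours are exposed. Untestable normality
(n < 3 or constant data) routes nonparametrically; fully degenerate
comparisons report p = 1 with route `"degenerate"`. All tests are two-sided
at α = 0.05, trends are read at 0.05 ≤ p < 0.10, and no multiple-testing
correction is applied — matching the source analyses.

`spearman_corr` uses mid-ranked Pearson correlation (tie-safe); for n ≤ 8 the
two-sided p is the exact proportion of all n! permutations with |ρ| at least
as large as observed, otherwise the t approximation on n − 2 degrees of
freedom. `chi_squared_proportions` is Pearson's X² without continuity
correction on a 2×2 table. `match_case_control` performs greedy 1:1 matching
within (sex, age-band) strata; bands are anchored at multiples of the width
(floor(age/5)·5 by default) — the anchoring is not published, so it is an
explicit, configurable convention — with pairs chosen by smallest absolute
age difference and ties broken lexicographically, making the matching
deterministic and order-independent. `percent_difference` is
100·(comparison − reference)/reference, rounded to one decimal for reporting,
the convention behind the published contrasts; `assemble_group_table`
produces the per-joint, per-parameter group summary (means ± SD, routed
p-values, percent differences) with ankylotic joints excluded.

Patient-level correlations and p-values are not reproducible — the underlying
per-subject data are not deposited — so they are covered by property-based
tests (exactness against enumeration oracles, type-I error of the routed test
under a null simulation at n = 16 vs 8 over 2000 replicates) rather than by
value reproduction.

## Numerical choices and problem sizes

- Grid anchoring: bone solids start and end on integer voxel planes, so
  integer-voxel gaps are exact; general gaps discretize within half a voxel.
- Morphology uses centre-sampled Euclidean balls (dilation: distance to
  foreground centres ≤ r; erosion: distance to background centres > r); grid
  borders are never background.
- Connectivity: 26 for components and adjacency, 6 for hole filling.
- Volume I/O: NIfTI stores voxel sizes as 32-bit floats; on reading they are
  snapped to 7 significant digits so round trips through files written by
  this package are exact. MetaImage support covers uncompressed local data;
  TIFF stacks carry the voxel size in a JSON sidecar.
- Test problem sizes were chosen to exercise every regime while staying
  desk-scale: plates at 30×30 lateral voxels, ball-and-cup heads of 1.2–2 mm
  radius on grids up to 130×130×96 voxels at the native 0.082 mm voxel size,
  oracle equivalence on 200 random connected masks of extent up to 24³, the
  null simulation at 2000 replicates, and cohort recovery at 10 000 subjects
  per group.

## Known limitations

- The JSW definition is one member of the sphere-fitting family; scanner
  vendors' exact filter chains are proprietary, so absolute values may differ
  from scanner software by sub-voxel amounts even when both are internally
  exact. The oracle tests pin this package's semantics, not the scanner's.
- The joint-space lateral boundary depends on the bridging radius; JSV is
  therefore convention-dependent (the mask is logged with its parameters),
  while the width statistics are insensitive to it by construction.
- The cohort generator reproduces first and second moments per parameter but
  not the joint dependence structure; statistics that rely on within-subject
  correlation (e.g. paired contrasts across joints) are conservative on
  synthetic data.
- Osteophyte phantoms lack analytic extrema; their effect on the width map is
  validated only qualitatively (added bone volume, bridging when long).
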