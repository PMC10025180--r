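# jswmorph

Three-dimensional joint-space morphometry for HR-pQCT imaging of finger
joints, written for researchers quantifying metacarpophalangeal (MCP) joint
damage — for example in hereditary hemochromatosis (HH) arthropathy, where
joint spaces become characteristically narrow and asymmetric.

High-resolution peripheral quantitative computed tomography (HR-pQCT) images
the MCP joints at an isotropic voxel size of 0.082 mm. From such a volume the
package:

1. segments the mineralized bone (fixed or Otsu threshold),
2. splits it into the metacarpal head and the phalangeal base, detecting
   bone-on-bone bridging and offering a programmatic analogue of the
   operator's manual correction,
3. fills each bone to its periosteal envelope (morphological closing + hole
   filling),
4. builds the joint-space mask between the two periosteal surfaces,
5. computes a local joint-space-width (JSW) map, and
6. summarizes it into the six standard parameters:

   | parameter | definition | units |
   |---|---|---|
   | JSV | joint-space voxel count × voxel volume | mm³ |
   | JSW | mean of the width map | mm |
   | JSW.SD | population SD of the width map (heterogeneity) | mm |
   | JSW.MIN, JSW.MAX | extrema of the width map | mm |
   | JSW.AS | JSW.MAX / JSW.MIN (asymmetry) | — |

The width map is maximal-inscribed-sphere local thickness over an exact
Euclidean distance transform: the width at a voxel *x* is the diameter of the
largest sphere that fits between the bone surfaces and covers *x*,

&nbsp;&nbsp;&nbsp;&nbsp;JSW(x) = 2 · max { r(p) : sphere(p, r(p)) covers x },
&nbsp;&nbsp;&nbsp;&nbsp;r(p) = d(p, bone surface),

with sphere centres sampled on the half-voxel grid, where the computation is
integer-exact (see the methods vignette for the discrete semantics). A
one-voxel gap measures exactly one voxel — the floor reported for this class
of algorithm on real scans is 0.082 mm — and slabs of any integer thickness
measure exactly their thickness.

Because no public image data exist for these joints, the package ships a
synthetic phantom generator (parallel and tilted plates, ball-and-cup joints
with osteophytes and contact patches, scanner-like blur and noise) with
analytic ground truth, plus a cohort synthesizer reproducing the published
group statistics of the HH study population. The study's quality-control
rules (motion grading, stack coverage, ankylosis exclusion), segmentation
bookkeeping, and statistics (Shapiro–Wilk-routed t / Mann–Whitney tests,
paired tests, chi-squared, Spearman correlations with exact permutation
p-values, 1:1 sex/age-strata case–control matching, percent contrasts) are
all implemented and tested.

## Worked example

Measure a synthetic joint with a known 1.0 mm gap:

```r
library(jswmorph)

ph <- make_phantom(phantom_spec("parallel_plate", gap = 1.0),
                   grid_spec(c(30, 30, 40)))          # 0.082 mm voxels
bones <- split_joint_bones(segment_bone(ph$volume, threshold = 0.5),
                           ph$grid)$bones
res <- measure_joint(bones)
res$morphometry
#>       jsv   jsw jsw_sd jsw_min jsw_max jsw_as ankylotic
#>  5.954774 0.984      0   0.984   0.984      1     FALSE
```

The 1.0 mm analytic gap discretizes to 12 one-voxel layers, so the measured
width is exactly 12 × 0.082 = 0.984 mm, constant over the whole gap (SD 0,
asymmetry 1), and the joint-space volume is the exact voxel count times the
voxel volume (30 × 30 × 12 voxels = 5.9548 mm³).

The published group contrasts recompute from the reference parameter table:

```r
pc <- published_contrasts()
pc[c(1, 8, 11), c("contrast", "reference_mean", "comparison_mean", "percent")]
#>                   contrast reference_mean comparison_mean percent
#>      jsv_men_vs_women_mcp2         112.73          141.39    25.4
#>  jswmin_women_vs_ctrl_mcp3           1.22            0.71   -41.8
#>     jswas_men_vs_ctrl_mcp3           2.78           12.75   358.6
```

HH men have a 25.4% larger MCP 2 joint-space volume than HH women; HH women
have a 41.8% smaller minimal JSW at MCP 3 than matched control women; HH men
show a roughly 4.6-fold (+359%) larger MCP 3 width asymmetry than matched
control men.

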