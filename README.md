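# gliovol

Volumetric response assessment of enhancing brain tumors from standard
pre-/post-contrast T1-weighted MRI.

## The problem

Diameter-based response criteria (RECIST's longest 1D diameter, the Macdonald
2D product *d*₁ × *d*₂) cannot describe residual tumor around a surgical
resection cavity: the enhancing tissue is a thin irregular rim, the cavity
collapses over time so every diameter shrinks even while the rim grows, and
subacute blood in the cavity is intrinsically T1-bright and mimics
enhancement. `gliovol` implements a nearly automated volumetric measurement
for exactly this setting, aimed at neuro-oncology imaging researchers and at
anyone building or validating serial lesion-volumetry pipelines.

## The algorithm

Given a pre-contrast volume *P*, a post-contrast volume *Q*, a gross tumor
outline *T* and a normal-parenchyma outline *N* (both drawn roughly by hand):

1. rigidly fuse *P* onto the grid of *Q* and form the subtraction map
   *S = Q − P∘φ*;
2. estimate the global brightness offset as the histogram **mode**
   *c = mode{ S(v) : v ∈ N }* and correct all values by it;
3. locate the nasal mucosa *M* automatically from a packaged atlas (affine
   template registration + label propagation; a manual outline can override),
   trim the top 5% of { *S(v) − c* : *v ∈ M* }, and set the enhancement
   threshold θ = 0.25 × (trimmed maximum);
4. count tumor-region voxels with *S(v) − c > θ*; the enhancing volume is
   the count × voxel volume, in cm³.

The mode correction makes the measurement invariant to additive inter-scan
brightness changes; the mucosa-referenced threshold makes it equivariant under
intensity scaling and recalibrates every scan, so different contrast boluses
and scanner settings do not masquerade as response or progression. RECIST and
Macdonald measurements of the same masks are provided for comparison, and a
geometric phantom generator supplies scan pairs with exact voxel-level ground
truth for every scenario (cavity collapse, subacute blood, meningeal rim,
serial series).

## Worked example

Generate a phantom with a 2 mm enhancing rim (true enhancing count 2032
voxels), Rician noise at 2% of rim contrast, and measure it with the full
pipeline — fusion, mode correction, atlas mucosa detection, threshold,
counting:

```r
library(gliovol)

ph  <- generatePhantom(phantomSpec(noise = "rician", sigma = 2, seed = 7L))
res <- quantifyEnhancement(ph$pre, ph$post,
                           tumor  = ph$truth@rois$tumor,
                           normal = ph$truth@rois$normal,
                           mucosa = ph$atlas)
res
#> EnhancingVolumeResult: 2032 voxels = 2.032 cm^3
#> EnhancementThreshold: 41.06 (= 25% of remaining max 164.3; top 5% of 168 mucosa voxels excluded)
#> CorrectionFactor: 7 (mode of 2688 normal-region subtraction values, bin width 1)
```

The correction factor recovered the phantom's +7 global post-scan offset, the
threshold (41.06) landed at 25% of the trimmed corrected mucosa maximum, and
all 2032 truly enhancing voxels — and no others — were counted: 2.032 cm³.
The conventional reading of the same lesion (cavity + rim):

```r
macdonaldMeasurement(ph$truth@cavityMask | enhancementMask(res),
                     voxelSpacing(ph$post))
#> DiameterMeasurement: 2.2 cm x 2 cm = 4.4 cm^2 (slice 27)
```

Serial scans are analyzed with `runSerial()`, which registers each follow-up
to the baseline and transfers the baseline outlines, and the worked clinical
diameter products reproduce with `bidimensionalProduct(4.3, 3.2)` → `13.8`
cm² and `bidimensionalProduct(3.7, 1.7)` → `6.29` cm². A command-line front
end (`measure`, `serial`, `phantom`) ships in `inst/cli/gliovol`.

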