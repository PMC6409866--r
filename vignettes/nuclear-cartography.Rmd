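---
title: "Nuclear cartography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear cartography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nucleocarta` maps fluorescence in-situ hybridisation (FISH) signals in
falciform — hooked — sperm nuclei. Because the mouse sperm head is
asymmetric along both the anterior–posterior and dorsal–ventral axes,
every signal position can be oriented unambiguously in 2D; the package
exploits that to replace manual region scoring with automated, pixel-level
mapping of signal distributions across whole cell populations. This
vignette explains the model behind each stage, the parameters that matter,
and the design decisions taken where more than one reasonable choice
existed.

## The pipeline at a glance

1. **Segmentation.** Nuclei are detected in the counterstain (DAPI)
   channel: Otsu threshold, hole filling, 8-connected components, then
   area, solidity and border filters.
2. **Landmarks.** Each outline gets a windowed interior-angle profile;
   its minima are the apical hook tip and the tail attachment site.
3. **Orientation.** Each nucleus is rigidly rotated (and mirrored if
   needed) into a canonical pose: hook-to-tail chord horizontal, hook on
   the left, dorsal side up.
4. **Consensus and mesh.** The population consensus shape is the
   pointwise mean of per-segment resampled outlines. A triangular mesh
   with identical graph structure is built on the consensus and on every
   nucleus.
5. **Warping.** Binarised signal rasters are moved face-by-face by the
   affine map between corresponding triangles, gap-filled, and aggregated
   into per-probe composite frequency maps.
6. **Comparison.** Composite and per-nucleus signal distributions are
   scored with MS-SSIM*; co-hybridised probe separations are measured as
   centre-of-mass distances and compared with Wilcoxon rank sum tests.

## Coordinate conventions

All rasters use the image convention: pixel (0,0) at the top-left, x
rightward, y downward, pixel centres at integer coordinates. Outline
boundaries, landmarks and meshes live in each nucleus's local frame, whose
origin within the source image is recorded as an `offset`. Orientation
stores its rigid transform explicitly so signal rasters, which stay in the
unoriented frame, can be carried through the warp without an intermediate
resampling step.

## The curvature functional and landmark rules

The angle profile assigns to boundary point $i$ the interior angle at
$p_i$ subtended by the boundary points half a window behind and ahead,
where the window is a fraction of the perimeter (default 5%, in boundary
points). The interior side is decided by an exact point-in-polygon test on
the chord midpoint. This windowed form is deliberately insensitive to
pixel-level boundary roughness: a discretised circle scores a flat profile
and a square's corners score 90 degrees, which the unit tests pin down.

Landmark rules, in order:

* `hook_tip` — global minimum of the profile (the sharpest convex
  protrusion). Ties break toward the smallest boundary index, so detection
  is deterministic.
* `tail_attachment` — the lowest-angle remaining local minimum at least
  25% of the perimeter away from the hook tip.
* Auxiliary extrema (`aux1`, ...) can be requested via
  `landmark_params(n_auxiliary = )`, subject to a minimum arc separation.
  The default is 0: nuclei swelled for hybridisation present few reliable
  extrema beyond the two required ones, and the number of auxiliary
  landmarks is a run parameter rather than a fixed property of the method.

Profiles whose global minimum is blunter than `hook_angle_max` (default
150 degrees) mark the nucleus unanalyzable and it is excluded — a circle,
for instance, has no orientable structure. Clumped nuclei are likewise
rejected rather than split: downstream composites aggregate over
populations, so losing clumps costs sample size, not correctness.

## Orientation

The hook-to-tail chord is rotated horizontal with the hook on the left. A
mirror is applied when the polygon centroid falls below the chord, so the
crescent always arcs dorsally over it with the hook curling upward; the
`flipped` flag records the mirror. The boundary is re-indexed to start at
the hook tip and traverse the dorsal side first. Orientation is idempotent
and mirror-equivariant, both of which are tested properties.

## Consensus and mesh construction

Each oriented outline is resampled to a fixed number of arc-length
equidistant points per inter-landmark segment; the consensus boundary is
the pointwise arithmetic mean. No Procrustes scaling is applied: nuclei
are already rigidly oriented, and residual size differences are biological
signal that should survive into the consensus.

"Equidistant" is read as equidistant in boundary arc length. Arc-length
spacing is stable under affine distortion of the outline and matches the
visual appearance of evenly spaced semi-landmarks.

The mesh: peripheral vertices are the landmarks plus
`semilandmarks_per_segment` semi-landmarks per segment (default 20, a
resolution choice, with ~160 boundary points per nucleus at the default
pixel size). Walking out pairwise from the hook tip, the i-th dorsal
vertex pairs with the i-th ventral vertex; each pair contributes an
internal vertex at its chord midpoint, tracing a midline skeleton from tip
to base. Faces are: two tip-cap triangles, two quads per band each split
along the diagonal toward the tip-ward internal vertex (any consistent
split satisfies the tiling invariant; this one is deterministic), and a
fan over the base cap which also absorbs excess vertices when the two
sides carry unequal counts. Every face is stored with positive
orientation, the faces tile the peripheral polygon exactly (area
conservation and zero pairwise overlap are tested on random populations),
and a chord midpoint falling outside the polygon marks the mesh degenerate
and the nucleus is excluded.

The mesh's `structure_signature` encodes landmark count and per-segment
semi-landmark counts — the quantities that fully determine face
connectivity — and deliberately ignores geometry. Two meshes are
warp-compatible iff their signatures match, which is what lets any
consensus (own-strain or another strain's) serve as the warp template.

## Warping and compositing

Signal channels are binarised *within the nucleus mask* before warping
(Otsu by default; fixed and fraction-of-maximum thresholds are available),
so bright and dim hybridisations contribute equally. Warping is a forward
map: each ON pixel centre is moved by its face's affine transform and
rasterised to the nearest target pixel. Forward mapping leaves holes
wherever a source face is smaller than its target face, which is exactly
what the gap-filling kernel addresses: in a single pass over a frozen copy
of the raster, any zero pixel with at least 4 non-zero 8-connected
neighbours becomes the mean of those neighbours (hence 1 for binary
rasters). Whether the filler should iterate is left configurable
(`fill_passes`, default 1 — one pass restores the identity warp to more
than 99% ON-pixel fidelity on fixtures, and determinism favours the
smallest sufficient count). The result is clipped to the target polygon.

Composites are per-pixel means of the binary warped rasters: frequencies
in [0,1] whose product with the population size is an integer count.
Random mispositioned signal averages toward the floor while consistent
addresses reinforce. The target raster frame is the template polygon's
bounding box plus a 2-pixel margin; all warps onto one template share it.

## MS-SSIM*

Similarity between signal rasters is the canonical five-scale structural
similarity: contrast/structure terms on successively 2x2-mean-downsampled
pairs, luminance at the coarsest scale, combined as a weighted geometric
product with exponents (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). Windows
are 11x11 Gaussian, sigma 1.5; stabilising constants default to K1 = 0.01,
K2 = 0.03 with the dynamic range taken as the maximum over the pair. The
`*` refinement matters for the degenerate windows that binarised and
composited rasters produce in abundance: where both images have zero
variance and equal means the component contributes 1 rather than an
indeterminate ratio. Identical images therefore score exactly 1. Images
too small for the full pyramid get a reduced scale count with a warning
and renormalised exponents; the constants are exposed because the exact
parameterisation of MS-SSIM* implementations varies between sources.

## Statistics

Centre-of-mass distances between co-hybridised probes use the
intensity-weighted centroid of the largest detected signal component per
channel (8-connected components above a fraction-of-maximum threshold,
default 0.5, minimum area 0.3 um^2 — both exposed, since no single
threshold suits all probe sets). Distance sets are compared with a
two-sided Wilcoxon rank sum test (normal approximation with continuity
correction; groups below n = 3 are refused). A 1000-replicate null
simulation in the test suite checks the test rejects at the nominal 5%
rate. One practical note: with only 3 observations per group a rank sum
test cannot reach p < 0.05 even under complete separation (the most
extreme exact two-sided p is 0.1), so the extreme-separation property is
exercised at n = 5.

## The synthetic generator

`generate_nucleus()` builds a falciform silhouette from a parametric
midline whose heading angle relaxes exponentially from a curled apical
hook (total turning about 140 degrees at `hook_curl = 1`) to a straight
body, with a half-width profile that pinches to a point at both the hook
tip and the tail end — so both landmarks exist by construction and their
true positions are recorded as ground truth. Defaults (length 10 um,
width 4.5 um, area ~32 um^2 at 0.1 um/pixel) emulate a DTT-swelled mouse
sperm nucleus, whose area roughly doubles into the 20–40 um^2 range during
hybridisation; the segmentation defaults (10–60 um^2) bracket that range.
The default pixel size, 0.1 um/pixel, corresponds to a 100x objective with
a cooled-CCD camera and modest binning.

Signal addresses use midline coordinates: u is the fractional arc position
from hook tip to base, v the signed fractional offset toward the dorsal
(+) or ventral (−) boundary. Addresses defined this way transfer across
differently shaped strains exactly as the mesh does, which is what makes
cross-strain tests meaningful. Named addresses `dorsal_apical` (0.30,
+0.45) and `ventral_basal` (0.75, −0.40) emulate the sub-acrosomal sex
chromosome territory and the basal/ventral autosome territory. Per-nucleus
biological scatter is an address jitter (SD 0.04 in address units), and a
`placement_noise` probability relocates the signal uniformly at random to
model failed or mispositioned hybridisation.

`generate_population()` places nuclei on non-overlapping grid cells with
random rotation, mirroring and jitter, and renders 8-bit channels: interior
counterstain 170 ± 8 over background 10 ± 3; signal blobs of amplitude 190
and sigma 0.45 um over background 6 ± 2.5. Fields carry at most two signal
channels, matching pairwise probe co-hybridisation; a four-probe experiment
is therefore simulated as two co-hybridisation batches warped onto one
shared consensus.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: chromatin texture and the DAPI-dense
chromocenter, acrosomes, partial swelling artefacts, clumped or
overlapping nuclei, uneven illumination, and channel bleed-through. Tests
against it validate the geometry and bookkeeping of the method, not the
segmentation's robustness to difficult real-world fields.

## Numerical choices and degenerate inputs

* Polygon rasterisation is scanline even-odd with half-open rules; areas
  in um^2 are interior pixel counts times the squared pixel size.
* Face assignment widens triangles by 1e-9 in barycentric coordinates;
  shared-edge pixels go to the lower face index.
* Zero-area source faces contribute nothing to a warp (with a warning);
  all-zero channels binarise to all-zero rasters without error.
* Equal-angle landmark ties break toward the smallest boundary index
  after the hook tip.
* Test-suite and example problem sizes (populations of 12–200 nuclei,
  consensus resampling at 100 points per segment) were chosen as the
  smallest sizes at which the population-level properties stabilise.

## Known limitations

* Only peripheral landmarks constrain the mesh; internal structure (e.g.
  DAPI texture) is ignored, limiting warp accuracy deep inside the
  nucleus.
* Touching nuclei are discarded, not split; heavily clumped preparations
  will lose many cells.
* Forward warping with nearest-pixel rasterisation plus majority gap
  filling is faithful to the described method but is not
  intensity-conserving; the non-binarised warp path exists but is not the
  default and should be interpreted with care.
* 2D projection only: territory overlap in z is invisible.
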