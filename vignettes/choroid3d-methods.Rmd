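---
title: "choroid3d: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{choroid3d: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
constants matter, what the synthetic test bed does and does not establish,
and where design latitude existed and how it was resolved.

## The measurement model

A wide-field SS-OCT volume is a stack of B-scans; within each A-scan the
choroid is the band between the choroidal–RPE junction (inner boundary) and
the choroidal–scleral junction (outer boundary). Large choroidal vessels —
the clinically interesting ones in pachychoroid disease — are hyporeflective
tubes embedded in brighter stroma. Four biomarkers are computed per eye, per
sector and globally:

* **CTh** (µm): `(outer − inner) × axial spacing`, averaged over a sector's
  en-face footprint.
* **CVI** (%): `100 × luminal voxels / choroid-band voxels`.
* **MChVD** (µm): mean of nine cross-sectional diameters per sector
  (3 seeded random sites × 3 largest vessels).
* **IVD** (µm): mean of nine edge-to-edge gaps from those vessels to their
  nearest independent neighbour.

The global value of each biomarker is the *unweighted* mean of the five
sector values, not the area-weighted volume mean: the sectors are the units
of clinical reporting, and equal weighting keeps the global summary
comparable across eyes whose fovea sits off-center in the scan.

## Boundary delineation

Per B-scan: normalize intensities to [0, 1] (this makes the pipeline exactly
invariant to global affine intensity rescaling), median filter, CLAHE, Otsu
binarization, 3×3 opening then closing, and largest-bright-component
analysis. The component's deepest row per A-scan is the outer boundary
estimate; the inner boundary is the bottom of the retina slab, separated
from stroma by a second Otsu threshold restricted to the bright component.
Raw estimates are smoothed with robust locally weighted regression (lowess)
along each B-scan and then again across B-scans per A-scan column — the
second pass is a deliberate stand-in, with matching smoothing intent, for
the tensor-voting surface regularizer used in earlier implementations of
this pipeline family.

Tunable constants (none are forced by the protocol itself, all are exposed
in `seg_params()`):

| parameter | default | why |
|---|---|---|
| `median_k` | 5 px | at speckle CV ≈ 0.5 a 3×3 median leaves too much sclera above the Otsu threshold; 5×5 still preserves 40 µm lumens |
| `clahe_tiles`, `clahe_clip` | 8×8, 1.2 | clip 1.2 limits how far CLAHE equalizes homogeneous (pure-noise) regions upward; larger clips pull sclera into the bright mask |
| `close_iter` | 8 | a 3×3 closing iterated 8× fills lumens up to ≈ 160 µm so they join the retina–choroid slab before component analysis |
| `open_iter` | 1 | removes isolated speckle specks before closing can amplify them |
| `lowess_f`, `lowess_iter` | 0.2, 3 | span small enough to track 300 µm undulations, robust iterations reject outlier columns |
| `max_failed_frac` | 0.25 | more than a quarter of B-scans without a candidate band aborts with a diagnostic |

A B-scan with no usable band (degenerate dynamic range, no bright component,
too few valid columns) is flagged `failed` and interpolated from its
neighbours. `apply_boundary_overrides()` replaces boundary positions verbatim
and marks the B-scan `corrected`; it is the hook standing in for both the
deep-learning segmenter of the original workflow (out of scope here) and the
human corrector that workflow still required for a few percent of eyes.

The per-column inner estimate takes the *deepest* retina run of length ≥ 2
rather than the largest run: under speckle the retina mask fragments, and
the largest fragment can end well above the true junction (a ~8 px bias in
our phantom experiments); stray single-pixel runs below the junction are
rejected by the length requirement and the robust smoothing.

## Vessel binarization

Phansalkar thresholding: a pixel is luminal iff its intensity is *strictly
below* `T = m · (1 + p·exp(−q·m) + k·(s/R − 1))`, with `m`, `s` the mean and
population standard deviation over a square window centered at the pixel.
"Overlapping windows" is implemented as a dense sliding window on every
pixel (integral images, edge replication) — not tiling. The 16 px window is
the one protocol-fixed constant; `k = 0.25, R = 0.5, p = 2, q = 10` default
to the constants of the method's original publication for low-contrast
images, and all are exposed in `binarization_params()`. The formula is
designed for dark-object detection in dim images: the `p·exp(−q·m)` term
raises the threshold where the local mean is low, which is exactly the
choroid's regime.

Post-processing: intersect with the choroid band, 3×3×1 in-plane opening
(1 iteration), then removal of 26-connected components below
`min_component_voxels = 50` (desk-scale default; scale with voxel volume for
other geometries). For even window sizes the window covers
`floor((w−1)/2)` pixels before and `ceil((w−1)/2)` after the center — the
brute-force oracle in the test suite pins this convention bit-exactly.

## Sector grid and 3D vasculature

The en-face plane is partitioned into a central disc of radius 2000 µm
around the fovea and four wedges cut by the two 45° diagonals: superior
(toward lower B-scan indices), inferior, and left/right mapped to
nasal/temporal by laterality. Pixels exactly on a wedge boundary are
assigned with fixed priority superior > inferior > nasal > temporal, making
the partition exact (a property test checks every pixel lands in exactly one
sector). The image-side convention for "nasal" is not universal in exported
scans, so it is configurable (`nasal_side`, default OD→image-right,
OS→image-left) and recorded on the grid object.

Optic-disc exclusion clears luminal voxels under an en-face circle or raster
footprint and is idempotent. Components are labelled with 26-connectivity;
volumes use the anisotropic voxel volume.

## Centerlines, diameters and IVD

The labelled vasculature is resampled to isotropic voxels (nearest-neighbour
for labels) at the smallest voxel dimension, skeletonized by a
topology-preserving 3D thinning (simple-point removal in six directional
subiterations, curve endpoints preserved), and each skeleton point is
annotated with the Euclidean distance transform value as its inscribed
radius.

Two numerical caveats are documented rather than hidden:

* The inscribed radius is exact to about half an isotropic voxel for
  grid-aligned straight tubes; for arbitrarily placed tubes the
  discretized cross-section is genuinely smaller than the nominal circle
  and the estimate inherits that (≤ 1 voxel) bias. The phantom generators
  therefore snap default tube axes to voxel centers — the stated world of
  the tests, not a calibration.
* Thinning leaves a short diagonal spur at *open tube end-caps* (where a
  vessel exits the volume); its radii are unreliable. Measurement sites
  therefore keep `l_min` (default 100 µm, configurable) away from curve
  endpoints as well as from branch points — the automated reading of
  "random sites on straight sections, avoiding bifurcations".

"Largest vessels" means largest luminal volume *within the sector
footprint* (a vessel crossing several sectors competes in each with only its
in-sector volume); the human graders judged size visually in 3D, and
in-sector volume is the reproducible, volume-proportional surrogate. Ties
break toward the lower component label. If a selected vessel exposes no
eligible straight run in the sector, the next-largest candidate is measured
instead, mirroring the protocol's "four or more vessels in cases of
uncertainty".

IVD is **edge-to-edge**: at a site, the distance to the nearest voxel of any
*other* 26-connected component minus the vessel's own inscribed radius.
Same-component collaterals are excluded by construction (connectivity), and
a sector with a single vessel reports IVD as missing, never zero. A
center-to-center variant was considered and rejected: the diameter
measurement reads outer edges, and mixing conventions would make
IVD − MChVD comparisons incoherent; the choice is recorded here and in the
object metadata.

**QC rule**: a vessel whose diameter (or IVD) triplet has sample SD > 50 µm
is redrawn with a freshly derived seed (base seed + attempt index), up to 5
attempts; the last triplet is kept with a `qc_max_attempts` flag if it never
settles, since the source protocol does not bound its "reassess and repeat"
loop. All randomness descends from one integer seed through named,
order-independent derived streams, so the whole protocol is reproducible and
two "graders" are simulated simply by two seeds.

## The synthetic test bed

`generate_phantom()` renders a four-slab scene — vitreous, retina, choroid
stroma, sclera at reflectivities 0.05 / 0.85 / 0.55 / 0.30 — between two
smooth random surfaces, with hyporeflective (0.15) capsule-geometry tubes in
the band. Surfaces are stationary Gaussian fields with a 300 µm correlation
length and 10 µm point SD, generated on an extended grid and scaled by the
theoretical SD of smoothed white noise (normalizing by the sample SD is
badly behaved when the field spans only a few correlation lengths).
Speckle is multiplicative unit-mean gamma noise, default shape 4 (per-voxel
CV = 0.5, a realistic post-log OCT contrast); note the [0, 1] clip truncates
the gamma tail, so a mid-grey voxel's expected value sits ≈ 1.3 % below its
clean intensity — the test suite asserts against the exact clipped
expectation.

The default desk-scale phantom (96 × 128 × 160 voxels at 10 µm isotropic,
288.9 µm mean band — a published cohort's mean choroidal thickness — and six
40–70 µm tubes) keeps the suite fast; `sector_phantom_spec()` provides a
6.3 × 6.3 mm field at 40 µm isotropic with twelve 110–180 µm tubes
populating all five sectors in three depth layers. Full clinical dimensions
(1024 B-scans of 1024 × 1536) are reachable through the same arguments. The
axial depth of a clinical 1536-sample A-scan is device-dependent and is
never hard-coded: axial spacing is always a configuration value.

What the phantoms do **not** emulate: spatially correlated speckle, depth
attenuation and vessel shadowing, partial-volume edge voxels, curved or
branching vascular networks, the choriocapillaris, and retinal layering
above the RPE beyond one uniform slab. A green recovery test therefore
establishes that the pipeline is *internally correct* (it recovers known
geometry under the stated noise model at stated tolerances), not that it is
accurate on clinical scans.

`generate_cohort()` draws per-eye biomarkers as `mean + sd · z` with
`z = √ρ·z_subject + √(1−ρ)·z_eye` injected at both the shared-across-sector
and per-sector levels, so paired eyes of one subject correlate at exactly
`ρ` (`within_subject_corr`, default 0.5 — a moderate anatomical concordance
between fellow eyes) in every sector. Sector values load on the shared
eye factor with `sector_loading = 0.9`, chosen because the published
per-sector and global SDs are nearly equal, which requires sectors of one
eye to move almost together; the global row is then *derived* as the mean of
the five sector rows, and its group mean matches the published global mean
because the reference table is internally consistent. A latent CTh–MChVD
coupling (`biomarker_corr = 0.55`, the published global correlation) enters
all latent factors. The bundled reference table keeps every published value
verbatim, including one sector SD that is visibly out of line with its
siblings; no default simulation or test depends on that entry.

## Statistics

`fit_group_lmm()` fits `value ~ group + (1 | subject)` by REML. The omnibus
group test is a **Wald F** on the group fixed effects with
`n_subjects − n_groups` denominator degrees of freedom, and pairwise
contrasts are t tests on the same df with Bonferroni multiplier 3 (the three
reported group comparisons), capped at 1. A likelihood-ratio test against a
chi-square reference was the original design choice but proved
anticonservative at realistic cohort sizes (a few dozen subjects): its
measured type-I error exceeded the 0.03–0.07 calibration band that the
acceptance suite enforces over 1000 null replicates, while the
between-subject-referenced F sits near 0.049. Shapiro–Wilk statistics are
reported per group on the model residuals; no automatic nonparametric
fallback is triggered, since the decision rule for one is not part of the
protocol. With no paired eyes the random intercept is unidentifiable and
the fit falls back to an ordinary linear model (subject = eye) with a note.
A zero-variance response short-circuits to "no group effect" (p = 1) rather
than a degenerate fit.

`icc_agreement()` implements the single-rater two-way random-effects
*absolute agreement* ICC(A,1) from the ANOVA mean squares, with the standard
F-distribution 95 % bounds, interpretation bands at 0.50 / 0.75 / 0.90, and
the consistency form reported alongside (a constant offset between graders
lowers absolute agreement but not consistency — a test pins this). Zero
total variance flags the ICC as undefined. `fisher_categorical()` wraps the
exact hypergeometric (2×2) / network (r×c) test and records which method
ran; the test suite verifies it against exhaustive enumeration on all small
tables.

## Degenerate inputs and tie-breaks (summary)

* Empty vessel mask → valid empty vasculature; sectors without vessels are
  flagged missing and excluded from the global mean with a warning — never
  imputed as zero.
* Sector with no band voxels → CVI missing, not 0 %.
* Constant-intensity volume → "no candidate band" abort.
* Volume-ranking ties → lower component label.
* Sector-boundary pixels → fixed priority superior > inferior > nasal >
  temporal.
* All seeds are 32-bit; derived streams use a deterministic string-hash of
  (operation, sector, vessel, attempt).

## Known limitations

The boundary pipeline assumes a bright retina above a mid-bright stroma
above a darker sclera; pathology that inverts these contrasts (large serous
detachments, dense hemorrhage) would require the override hook. The
inscribed-radius diameter underestimates non-circular (e.g. flattened)
lumens. IVD at coarse lateral pitch inherits up to a voxel of rasterization
error. The statistics stage reproduces the *procedures* of the clinical
study; its clinical group values derive from private scans and are used here
only as generator parameters, never as expected outputs.
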