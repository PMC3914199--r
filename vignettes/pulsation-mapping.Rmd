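---
title: "Mapping and measuring retinal vessel pulsation from ECG-gated fundus sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and measuring retinal vessel pulsation from ECG-gated fundus sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal vessels change caliber rhythmically with the cardiac cycle:
spontaneous venous pulsation near the optic disk, arteriolar pulsation,
serpentine motion of larger trunks. The changes are small — a few
micrometers on vessels of 90–115 µm, i.e. fractions of a pixel at typical
fundus resolutions (~7.9 µm/px) — so they are invisible in a single
photograph and easily drowned by inter-frame eye motion and uneven
illumination.

`retinapulse` implements a gated-acquisition analysis chain for this
setting. One frame is captured at each of `n_phases` (default 8) equal
subdivisions of the ECG R-R interval, the first at the R peak
(`trigger_schedule()`); a ninth trigger would coincide with the next R
peak and is redundant. An alarm flags acquisitions whose R-R interval
drifts by more than 10% from baseline (`check_rr_stability()`, strict
inequality at the boundary), since drifted triggers land at the wrong
cardiac phases.

The chain is:

1. **Rigid alignment** of the green-channel frames to the R-peak frame
   (`align_sequence()`).
2. **Bilateral denoising** and a **vesselness map** per frame — the
   gradient magnitude of the Hessian-orientation field, high at vessel
   edges and insensitive to slow illumination drift
   (`compute_vesselness()`).
3. A **binary vessel mask** from Gabor-wavelet features and a Bayes pixel
   classifier, cleaned morphologically and multiplied into the maps
   (`build_vessel_mask()`, `mask_vesselness()`).
4. **Caliber measurement**: seed-based edge tracking with moving circles,
   shortest-distance cross-section pairing, mean cross-section length,
   micrometer calibration (`track_edge()`, `pair_cross_sections()`,
   `segment_diameter()`, `calibration_factor()`).
5. **Trend aggregation**: DTW alignment of per-vessel 8-point trends,
   per-point averaging, variations against cardiac point 1, max–min,
   peak point, and a repeated-measures ANOVA (`average_trends()`,
   `trend_summary()`, `rm_anova()`).
6. **Playback**: concentric zones around the optic disk and a looped
   frame schedule on which graders can see the pulsation
   (`make_zone_map()`, `assemble_playback()`).

`run_pipeline()` sequences all stages from one config;
`inst/cli/retinapulse.R` is a thin shell entry point over it.

Coordinates are 0-based and pixel-centered, `x` along columns, `y` along
rows (down); angles are degrees counterclockwise from +x in that frame;
intensities live in [0, 1] with vessels darker than background, as in the
green channel.

## The vesselness map

At a fixed scale `sigma_px` the Hessian of the smoothed intensity is
computed per pixel from derivative-of-Gaussian kernels
(`hessian_field()`). Inside a dark vessel the eigenvector of the
small-magnitude eigenvalue points along the vessel and the large one
across it; outside, the roles invert. The vesselness map is the spatial
gradient magnitude of an orientation field derived from this eigen
structure: where the inside/outside roles swap — the vessel edge — the
orientation jumps and the gradient responds.

Two orientation formulations are provided (`orientation_map()`):

* **`"principal"` (default)** — the orientation of the principal axis of
  the traceless Hessian, `atan2(2·Ixy, Ixx − Iyy)/2` mod π. Crossing a
  vessel edge swaps which eigenvalue dominates, so this angle jumps by
  π/2 exactly at the edge, for *every* vessel direction, and it involves
  no eigenvector sign conventions.
* **`"eigvec_sum"`** — each unit eigenvector is sign-canonicalized
  (x ≥ 0; if x = 0, y ≥ 0), the two are summed, and the resultant's angle
  is taken mod π.

The second form is the more literal "sum of the two eigenvectors", but it
has a structural weakness that drove the default: the *set* of the two
orthonormal eigenvectors does not change at the edge (only the eigenvalue
labels swap), so the canonicalized unit sum is constant across an ideal
oblique edge and responds only where an eigenvector crosses the
canonicalization seam (x = 0). For near-axis-aligned vessels that seam
runs through the whole vessel band, where the tiny noise-dominated `Ixy`
flips the sum pixel-by-pixel — saturated speckle instead of an edge
ridge. The principal-axis form keeps the intended physics (the role swap)
and none of the seam artifacts. Both orientations live in [0, π); the
gradient uses central differences with circular differencing modulo π
(`d(a,b) = ((a − b + π/2) mod π) − π/2`), so the wrap at 0/π creates no
false ridges; a Sobel variant sits behind `operator = "sobel"`.

Away from edges the orientation is still noise-driven wherever the image
is flat, which is why the map must be masked before measurement — the
mask stage is integral to the method, not cosmetic.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `sigma_px` (Hessian scale) | 2 px | matches 6–16 px vessel widths implied by ~7.9 µm/px and 90–115 µm calibers |
| `sigma_spatial_px` (bilateral) | 3 px | removes sensor noise without flattening 10 px-scale structure |
| `sigma_range` (bilateral) | 0.1 | ~10× the typical noise SD: averages noise, preserves the ~0.2–0.4 vessel contrast step |
| Gabor `scales` | 2, 3, 4 px | brackets the half-widths of the target vessels |
| Gabor orientation grid | 0°–170°, step 10° (18 angles) | orientation sweep of the wavelet transform |
| Gabor elongation / frequency | ε = 4, k0 = (0, 3) | standard elongated-Morlet settings for curvilinear structure |
| `n_dilations` | 5 (3×3 square) | widens the mask by 5 px so the ridge band survives masking |
| tracker `radius_px` / `step_px` / `snap_radius` | 4 / 2 / 5 px | probing circle spans the ridge, step is half the radius, snap covers a sloppy click |

## Segmentation and classification

The feature stack per pixel is the standardized inverted intensity plus,
per scale, the maximum over the 18 orientations of the modulus of the
complex Gabor transform (zero-mean kernels, so constant regions give no
response). A Gaussian (mixture) is fitted per class; with the default
`k = 1` the fit is closed-form and fully deterministic. Priors are the
labeled pixel fractions; classification is the Bayes rule with exact ties
going to background — a conservative mask costs little (dilations restore
cover) while a permissive one admits background speckle. Near-singular
covariances receive a `1e-6` identity ridge. Training labels come from
the phantom's ground-truth mask; the classifier generalizes across
phantoms drawn with different seeds (tested at ≥ 0.9
sensitivity/specificity). Isolated foreground pixels are removed before
dilation, as speckle cannot be an edge; a full 3×3 opening is available
behind `opening = TRUE`.

The mask is built once on the reference frame and reused (the sequence is
aligned); `mask_per_frame = TRUE` switches to per-frame masks.

## Registration

Translation is estimated by windowed FFT phase correlation with parabolic
sub-pixel interpolation; rotation by a bounded golden-section search
(±3.5° by default) maximizing the post-alignment normalized
cross-correlation; estimation runs on 2× block-downsampled frames and the
result is polished by a Nelder–Mead ascent of the central-region NCC at
both resolutions. The polish matters: phase correlation whitens the
spectrum, which under-weights sparse structure and lets the translation
slide along a dominant vessel direction; the NCC objective restores that
information. Frames register pairwise to the single reference frame (no
chaining, no drift accumulation); resampling is bilinear with
out-of-frame pixels filled by the frame median. A normalized correlation
peak below `min_peak` raises a registration-failure error naming the
frame. One genuine limit: a scene whose only structure runs in a single
direction leaves the along-structure translation component weakly
determined — real fundus frames, with vessels radiating in many
directions, do not suffer this, and the bundled phantoms include
differently oriented vessels for the same reason.

## Caliber measurement

A grader supplies one approximate point near each vessel boundary and the
segment's start and end points (`seed_spec()`); the same seeds are reused
at every cardiac phase. The tracker snaps the seed to the strongest ridge
within `snap_radius`, then walks: a probing circle of `radius_px` samples
the masked map on the forward ±60° arc (the backward arc is excluded),
the best direction is taken, and the center advances `step_px` along it,
after which the point is re-locked onto the local ridge maximum within
±2 px across the travel direction. Decisions are made on a σ = 0.8 px
smoothed copy of the map — symmetric smoothing attenuates residual
speckle without moving the straight ridge. The walk runs from the seed to
each endpoint in turn and stops once within `step_px` of the endpoint or
past its projection along the segment axis (edge ridges run parallel to,
not through, the clicked endpoints). Each tracked point is refined by a
3-point parabolic fit across the local normal: the pulsation amplitudes
of interest are sub-pixel, so integer ridge positions are not enough.

Cross-sections pair each point of edge 1 with its nearest point on edge 2
(ties to the lower index; a mutual-nearest filter is available for skewed
endpoints); the segment diameter is the arithmetic mean of the
cross-section lengths, converted to micrometers by the calibration factor
`reference_um / od_macula_distance_px` with `reference_um` defaulting to
4500 µm (2.5 average optic-disk diameters).

A measurement subtlety the cross-section averaging is designed around:
on an *exactly* axis-aligned straight vessel the orientation step at the
edge falls between two pixel rows and its sub-pixel position is not
recoverable from the gradient values, so individual cross-sections
quantize toward integer widths. Oblique or curved vessels — the realistic
case — sweep the edge's sub-pixel phase along the segment, and the mean
over ≥ 30 cross-sections recovers the sub-pixel width. The phantoms used
in tests run obliquely for this reason, and measured segments should be
chosen away from exact horizontal/vertical when sub-pixel amplitudes
matter.

## Trends and statistics

Per-vessel 8-point trends are aligned by classic DTW (squared-difference
cost, steps {(1,0), (0,1), (1,1)}, pinned ends) to remove the
location-dependent phase lag between measuring sites; the reference trend
is the per-class DTW medoid (smallest mean cost to all others), a
symmetric, deterministic choice. The cyclic-DTW variant was considered
and left out: the standard algorithm is the cited one, and an 8-point
cycle gives the warping path little room anyway. Aligned trends are
averaged per cardiac point; the summary reports |mean_i − mean_1| for
i = 2..8, max–min, the (first-on-ties) peak point, and the
repeated-measures ANOVA p-value computed from the textbook within-subject
partition (F = MS_condition/MS_error with (k−1, (k−1)(n−1)) df).
Degenerate inputs with zero residual *and* zero condition variation
return F = 0, p = 1. Greenhouse–Geisser correction is implemented behind
`gg_correction = TRUE` but off by default; post hoc comparisons are
paired t-tests against point 1 with Bonferroni correction
(`posthoc_vs_first()`), chosen as the simplest procedure matching the
"variations vs point 1" table structure. Reported summaries round half-up
to 1 decimal (quality scores additionally to the nearest integer), the
convention of the bundled tables.

The package ships the printed summary tables of a twelve-subject gated
fundus study (`example_table()`): per-point caliber means/SDs measured
with and without pulsation playback, and per-subject grader counts of
pulsatile features with ten-point quality scores under the proposed
playback versus a principal-component baseline. The subject-level raw
images behind them are not distributable, so these tables are worked-example
*inputs*: the package reproduces the arithmetic printed alongside them
(max–min values, increases between methods, peak points, quality means),
not the measurements themselves.

## The phantom

`render_phantom()` draws, per cardiac point, dark curvilinear vessels of
known width over a bright background with a smooth multiplicative
illumination field (radial vignette + linear tilt), a soft-rimmed bright
optic disk, per-frame rigid eye drift, and additive Gaussian noise; the
full ground truth (widths per phase, centerlines, motions, geometry, true
vessel mask) is returned alongside. Width pulsates as a raised cosine —
any unimodal periodic waveform would do; the cosine makes peak, trough
and peak-to-trough (= 2·amplitude) exact. The cross-profile is a
rectangle convolved with a Gaussian (σ = 1 px), implemented analytically
through the error function of the centerline distance, so "true width"
has an exact half-depth meaning and rendered widths are sub-pixel
accurate. Eye drift defaults to a few pixels and fractions of a degree
(`random_motions()`) — the magnitude that makes registration necessary,
comparable to the pulsation itself.

What the phantom does *not* emulate: the central light reflex of real
arterioles, vessel crossings and branchings within a measured segment,
non-rigid deformation, focus changes, and flash-to-flash illumination
jitter. Passing the recovery suites therefore shows the chain is correct
and sub-pixel capable on controlled geometry, not that it is robust to
every clinical artifact.

Problem sizes: unit and acceptance tests run phantoms of 140×220 to
200×260 px with one to four vessels — large enough for ≥ 30 cross-sections
per segment and honest optic-disk/illumination context, small enough to
iterate quickly. The same chain runs unchanged at the 512×1024 default of
`phantom_config()`.

## Reproducing the study arithmetic

```{r}
library(retinapulse)

calibration_factor(569.1)$um_per_px        # ~7.90 um/px

vis <- example_table("visualized")
art <- vis[vis$vessel_class == "arteriole", ]
trend_summary(art$mean_um, art$sd_um)       # max-min 3.3 um, peak point 2

gs <- grader_table_summary(example_table("grader_counts"))
gs[gs$feature == "QOF", ]                   # quality 3.0 (PCA) vs 6.9
```

`scripts/acceptance.R` recomputes these together with the phantom
recovery metrics; see the README for how to run it.

## Known limitations

* Sub-pixel caliber on exactly axis-aligned straight segments quantizes
  (see above); choose oblique segments or rely on many cross-sections.
* The vesselness map is undefined-by-design in flat regions; measurements
  are only meaningful on the masked map.
* Registration assumes rigid motion; residual non-rigid deformation
  becomes caliber noise.
* The Bayes classifier is as good as its training labels; on real data it
  would need manually labeled pixels in place of phantom truth.
* RM-ANOVA assumes complete cells; vessels missing a phase must be
  excluded before `average_trends()`.
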