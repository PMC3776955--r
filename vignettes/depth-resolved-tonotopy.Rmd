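---
title: "Depth-resolved tonotopy analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved tonotopy analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tonodepth)
```

## The problem this package addresses

The inferior colliculus (IC), the principal auditory midbrain nucleus, is
tonotopically laminated: electrophysiology in animal models shows
preferred sound frequency advancing from superficial, dorsal tissue to
deep, ventral tissue. The IC is small (under 9 mm across) and sits in a
region where functional MRI is noisy, so resolving this *depth-wise*
organization non-invasively requires high-resolution imaging (about
1.2-mm voxels), sparse-sampling acquisition around quiet stimulus
periods, and an analysis that respects the geometry of the structure
rather than treating voxels as an unordered set.

`tonodepth` implements that analysis as a reusable pipeline:

1. a triangulated surface model of the tissue boundary, with outward
   normals, per-vertex areas and mean curvature
   (`extract_surface()`, `curvature_and_region()`);
2. a nearest-vertex Euclidean depth map assigning every tissue voxel a
   depth coordinate (`compute_depth_map()`);
3. per-voxel frequency responses: quiet-referenced amplitudes per sound
   condition, the amplitude-weighted **centroid frequency**

   $$f_\mathrm{cent} = \frac{\sum_i f_i\,A(f_i)}{\sum_i A(f_i)},$$

   the second-moment **tuning width**, the high-minus-low amplitude
   difference, and bootstrap uncertainty for all of them
   (`extract_amplitudes()`, `centroid_frequency()`, `tuning_width()`,
   `centroid_ci()`);
4. **virtual penetrations**: 1.2-mm-diameter cylinders extended along
   the inward mean surface normal of a 0.6-mm manifold patch at every
   analysis-region vertex, a straight-line fit of centroid frequency
   against depth after removing 0--1.5 mm of superficial tissue, and a
   one-sided bootstrap p value for the slope (`build_penetration()`,
   `fit_depth_gradient()`, `bootstrap_slope_p()`, `map_gradients()`);
5. whole-structure summaries: areas of significant (p < 0.05) and
   trend-level (p < 0.16) gradients, the slope-weighted mean gradient
   direction with sagittal/axial angles, and a per-session report table
   (`gradient_summary()`, `area_summary()`, `mean_gradient_direction()`,
   `table_stats()`).

Because no suitable public dataset carries this acquisition, the package
ships a first-class synthetic phantom (`phantom_spec()`,
`make_phantom_mask()`, `plant_frequency_field()`, `simulate_session()`)
whose planted parameters the pipeline must recover, plus a simulator of
the behavioral protocol run in the scanner: interleaved two-up/one-down
staircases on a two-interval frequency-discrimination task
(`run_staircase_session()`).

All frequency quantities are carried in log2 frequency ("octaves re
1 kHz"): the stimuli are logarithmically spaced and gradients are
reported in octaves/mm, which linear-frequency moments could not
produce. Geometry is in physical millimeters with axes
(x = right, y = anterior, z = superior) and voxel centers at
`(index - 0.5) * voxel_size`.

## The phantom: what it emulates and why these defaults

The phantom is a brainstem slab carrying two superior half-ellipsoid
"colliculi" on a 1.2-mm isotropic grid. Defaults encode the study
conditions the analysis is meant for:

| parameter | default | rationale |
|---|---|---|
| `voxel_size_mm` | 1.2 | the acquisition resolution of interest |
| `colliculus_radii_mm` | (4.5, 4.5, 4.5) | 9-mm spherical colliculi, the upper end of human IC size; spherical caps make the analytic depth exact and give penetrations 3--4.5 mm of tissue run |
| slab below the caps | ~9.6 mm thick | the brainstem continues far below IC; a thin slab would artificially cap the depth coordinate |
| `rind_thickness_mm` | 0.7 | superficial non-tonotopic tissue (the external-cortex analog), within the 0--1.5 mm band the fits search over |
| `gradient_oct_per_mm` | 0.53 | the planted depth slope, the central literature value for this structure |
| `base_freq_oct` | -0.5 | preferred frequency at the rind bottom; centers the planted range inside the 5-octave stimulus band so centroid compression at the band edges stays small |
| `tuning_width_oct` | 1.0 | Gaussian tuning in log2 frequency; a voxel pools millions of neurons, so octave-scale population tuning is realistic, and edge-preferred voxels naturally produce low-/high-pass response shapes |
| `snr` | 25 | thermal temporal SNR of the images |
| `n_runs`, `reps_per_run` | 11, 5 | 55 presentations per condition per session |
| `response_amp_pct` | 2.5 | peak evoked amplitude, percent of baseline; calibrated so the per-voxel centroid bootstrap intervals approach the stability reported for real data (see below) |
| `patch_fraction`, `patch_scale_mm` | 0.7, 3 | tonotopy is patchy; see the patch-model note |
| `gain_amp` | 0.2 | a smooth multiplicative coil-gain field, so homomorphic normalization has real work to do |

Amplitude calibration: at 1% peak amplitude the simulated centroid
estimates are markedly less stable than published measurements of this
kind (bootstrapped 68% intervals averaging ~0.9 octaves rather than
under 0.5). Published response-difference profiles at these field
strengths span 2--3% signal change, and with 2.5% peak amplitude the
phantom's mean centroid interval falls to ~0.6 octaves. We set 2.5% as
the default and note that the phantom remains slightly noisier, per
voxel, than the best real data.

Each presentation contributes one scalar amplitude volume: the sparse
design is built to sample the flat top of the evoked response, so the
plateau sample *is* the data product. Noise is Gaussian (at SNR 20--30
the magnitude-image noise is effectively Gaussian), independent across
voxels and presentations. An optional hemodynamic undershoot carry-over
(`undershoot_frac`) subtracts a fixed fraction of the preceding
condition's response; it is off by default.

**Patch model.** Patches are seeded contiguous azimuthal wedges about
each cap center. Any tiling with *elevation* structure is inconsistent
along penetrations: cylinders entering at different elevations converge
under the cap apex, so a deep voxel cannot belong to one elevation tile
per penetration. Azimuth, by contrast, is invariant along radial
penetrations at every depth, including the sub-cap column, so wedge
labels are penetration-consistent while still giving patchy surface
coverage. The residual limitation is real: near the cap axis all wedges
meet, and cylinders that straddle wedge boundaries mix planted and
untuned tissue. This is why the patch-fraction correspondence
("significant fraction tracks planted fraction") is checked coarsely
(within 0.2, plus a strong discrimination requirement), and why the
slope-recovery experiment plants the gradient over the whole cap
surface (`run_recovery_experiment()`, `patch_fraction = 1`) --- the
recovery property concerns the estimator, not the tiling.

The ground-truth depth is computed analytically from the phantom
geometry (ellipsoid surface projection, rim and box faces), never
through the surface module, so depth-map errors cannot cancel out of
the recovery comparison.

## The analysis grid

The penetration geometry (0.6-mm cylinder radius, at least 4 points per
fit) is unusable on the native 1.2-mm grid: a cylinder of radius 0.6 mm
contains only ~3 voxel centers over 5 mm of depth. Real analyses of
this kind align the functional data to a finer structural reference
before surface sampling; the pipeline mirrors that by resampling the
per-condition amplitudes onto a 0.6-mm analysis grid
(`analysis_grid()`, mask-aware trilinear interpolation) on which the
depth map and cylinder membership are computed. Bootstrap resampling
stays at the presentation level, so the spatial correlation introduced
by interpolation propagates into the resampled fits and does not bias
the p values. The interpolation operator is exposed as a sparse matrix,
and the same operator is applied to point estimates and to every
bootstrap resample.

## Numerical choices

* **Isosurface**: marching tetrahedra (six tetrahedra per cell, shared
  edge vertices, outward-consistent orientation) on the voxel-center
  lattice, after a light Gaussian pre-smoothing of the binary volume
  (FWHM 1.2 voxels) that positions the 0.5 isolevel with sub-voxel
  accuracy; then 20 iterations of volume-preserving Taubin smoothing
  (lambda 0.5, mu -0.53). On a digitized 10-mm sphere at 1-mm voxels
  the area converges to within ~1% of closed form.
* **Curvature**: the directional derivative of the (regularized) vertex
  normal field along edges, averaged per vertex --- exact on spheres ---
  followed by short area-weighted smoothing. The regularization length
  must stay below the feature scale: heavy smoothing drags the concave
  cap--slab crease into the cap and erases it. With the default two
  passes the estimate is noisy per vertex, so region selection applies
  morphological closing on the mesh graph before keeping the largest
  connected components. A known limitation follows: the curvature
  region recovers the *convex portion* of each cap; a collar of
  roughly 1--1.5 mm above the smoothed crease has non-positive
  curvature and is excluded, so region areas run ~20--30% below the
  analytic cap area at this resolution.
* **Manifold distance** is the shortest edge path (Dijkstra), an upper
  bound on the true geodesic; at a 0.6-mm radius on ~0.5--1-mm edges
  patches are small and the bound is tight enough for normal averaging.
* **Depth** is the distance to the nearest mesh *vertex* (as the method
  prescribes), which overestimates the distance to the surface by up to
  about half the vertex spacing; the bias is nearly uniform and mostly
  drops out of slope fits.
* **Initial-depth search**: d0 runs over 0--1.5 mm in 0.1-mm steps,
  each fit needs at least 4 voxels, the maximal R^2 wins and ties break
  toward smaller d0 (keeping more data). The search is a maximization
  over 16 correlated windows and therefore inflates both the spread and
  the magnitude of fitted slopes on short noisy profiles; this is a
  property of the published procedure itself and is visible in the
  null calibration (below).
* **Bootstrap slope p**: 1000 presentation-level resamples per
  condition; each resample's voxel values are recomputed (the min
  subtraction is applied inside every resample) and refit with d0 held
  fixed at the point estimate --- re-searching d0 per resample would
  bias p downward. p is the fraction of non-positive slopes, clamped to
  at least 1/(B+1); significance is one-sided for positive gradients,
  with a mirrored test for reversed patches. No multiple-comparison
  correction is applied across vertices.
* **Centroid moments** use min-subtracted amplitudes; profiles that are
  exactly constant have undefined moments and are flagged rather than
  mapped. The min subtraction makes the centroid invariant to additive
  offsets (so the quiet reference and any residual baseline drop out)
  but pulls noisy centroids toward the grid center --- the main source
  of slope attenuation in recovery, alongside the finite tuning width
  and depth-map error. Recovered mean slopes on the phantom sit ~15%
  below the planted value, inside the recovery tolerance.
* **Preprocessing**: homomorphic normalization divides by a spatially
  smoothed temporal mean computed by normalized convolution restricted
  to the tissue support (plain smoothing across the tissue--air boundary
  would corrupt exactly the superficial voxels this analysis cares
  about); high-pass filtering removes DCT components below 2 cycles/run
  within each run and re-adds the mean as 100, leaving the 5-cycles/run
  stimulus structure untouched.
* **Null calibration**: a clean null phantom plants a *constant*
  preferred frequency with no rind (with a rind present, the step
  between untuned rind centroids and planted tissue is structure, not
  null). On it, the centroid-based test runs mildly conservative
  (false-positive fraction ~2--3%; the per-resample min subtraction
  inflates the bootstrap slope spread relative to the point estimate's
  sampling spread) while the linear high--low-difference variant runs
  mildly liberal (~5--7%; the d0 search selects extreme windows).
  Because penetrations within one session share a noise field,
  per-session fractions are strongly correlated and scatter by several
  percent; calibration therefore pools several independent sessions and
  both variants of the same test.
* **Report display** rounds half-up at the conventional precision
  (areas and angles to integers, slopes/R^2/depths to two decimals);
  computed statistics are kept unrounded everywhere else.

## Problem sizes

The validation suite runs phantoms of ~2700 tissue voxels (24 x 16 x 15
grid), 330-presentation sessions, ~480 region vertices with B = 1000
bootstrap resamples per penetration, and averages the recovery
experiment over three independent sessions and the null calibration
over twelve; geometry oracles run on toy blocks and digitized spheres
where brute force is exact. These sizes keep a full validation run in
minutes on one CPU while leaving every statistical check at its stated
strength.

## What the synthetic validation does and does not show

Passing recovery on the phantom shows that the *chain of estimators* ---
surface, depth map, centroid moments, penetration fits, bootstrap
inference, summaries --- is internally consistent, correctly seeded, and
recovers a planted laminar gradient at realistic noise, amplitude,
geometry and trial counts, with calibrated false positives under the
null. It does not validate the hemodynamic or physiological realism of
real midbrain data: the phantom has no physiological noise (cardiac or
respiratory), no motion, no draining-vein geometry, Gaussian tuning of a
single width, noise that is white in space and time, and patchiness of
a single angular form. Conclusions about real tissue still require the
controls the method itself carries (sound-versus-quiet significance,
the blur control, reversed-gradient tests) on real measurements.
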