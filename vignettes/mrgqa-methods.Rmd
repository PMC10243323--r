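---
title: "Methods: cine motion tracking and commissioning QA for an MR-linac brain treatment package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cine motion tracking and commissioning QA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgqa)
```

`mrgqa` collects the computational pieces of commissioning a dedicated
brain coil plus stereotactic immobilization package on a low-field MR-linac:
tracking head motion in planar cine MRI, the ACR large-phantom image-quality
metrics, the attenuation bookkeeping for the immobilization hardware, and
rigid 3D registration for inter-fraction setup variability. Everything is
validated on synthetic digital phantoms with exact ground truth, because the
underlying volunteer and phantom scans are not public. This vignette
documents the models, the defaults, and the choices made where the design
was genuinely open.

## Coordinate and transform conventions

Pixels are indexed 1-based, R style; the physical position of pixel
`[r, c]` is `x = (c-1) * spacing_col`, `y = (r-1) * spacing_row` in mm.
Volumes are arrays `[lateral, AP, SI]` with x to the patient's right, y
anterior-to-posterior, z inferior-to-superior. An in-plane rigid motion is
`T(p) = R(theta) (p - c) + c + t`, counterclockwise-positive, applied about
a stated center; 6-DOF rotations are yaw (SI axis), then pitch (lateral
axis), then roll (AP axis), extrinsic. `apply_rigid_2d()` and
`apply_rigid_3d()` resample `in(T^{-1}(q))` with bilinear/trilinear
interpolation, so the result is the image of the anatomy *after* the
motion, and the stored schedule is exactly the transform a registration
should recover.

## The synthetic head phantom

`phantom_spec()` describes an axial head cross-section: a bright elliptical
skull ring (default outer semi-axes 65 x 80 mm, 6 mm thick, intensity 200),
brain parenchyma (120) and two dark lateral ventricles (40) offset 13 mm
from midline, on a 160 x 160 grid of 1.3 mm pixels — the brain-coil cine
resolution; 3.5 mm emulates the torso-coil cine. The volumetric analogue
(`phantom_spec3d()`) uses 64 x 64 x 48 voxels at 3 mm.

Noise is the MR magnitude model: two Gaussian quadrature channels of SD
`noise_sd` (default 4), giving Rician noise over anatomy and a
Rayleigh-distributed background whose SD is about 0.655 of the channel SD —
which is exactly what the 0.66 factor in the SNR formula corrects for.
Crossline artifacts — the bright line an interleaved orthogonal-plane
acquisition leaves in a frame — are modeled as a full image row or column
scaled by a constant factor (default 1.5); the real artifact's intensity
profile is not characterized, so the scale factor is a stated surrogate.
The generator does not emulate coil sensitivity profiles, k-space sampling,
susceptibility distortion, or through-plane motion, so passing tests
demonstrate correctness of the algorithms under rigid in-plane motion with
stationary noise, not performance on every clinical contingency.

Motion schedules are first-class objects. `schedule_session()` builds
labeled segments (e.g. "gentle", "forceful") in which each degree of
freedom follows a smooth half-sine-squared excursion whose maximum equals
the programmed maximum exactly, so per-segment summary tables have an exact
ground truth. `project_schedule()` maps a 6-DOF schedule onto the three
orthogonal planes with the same axis mapping the tracker uses.

## The cine tracking pipeline

`track_sequence()` runs, in order: (1) crop the constant-intensity system
border (`margin = "auto"` detects the per-side run of constant lines; a
noiseless synthetic background is indistinguishable from such a border, so
pass `crop_margin = 0` for noise-free frames); (2) detect the target
contour on the first frame — Otsu threshold within an optional search box,
largest connected component, 1-px perimeter — plus a gating boundary at the
configured margin (default 3 mm); (3) fill the contour by
dilate-fill-erode with matched radii, and take its centroid as the rotation
center; (4) optionally inpaint burned-in contour overlays by iterative
neighbor averaging (off by default: the synthetic frames carry no burned-in
graphics, and inpainting clean frames only discards skull-edge signal;
enable it for console video exports); (5) detect crossline artifacts per
frame; (6) build the registration ROI as a skull-band annulus — the filled
target dilated 2 mm minus the target eroded 9 mm — minus any
reference-frame artifact lines; (7) register every frame to the first by
exhaustive coarse-to-fine search over (dx, dy, theta), scored by the
Pearson correlation between reference ROI pixels and moving-image pixels
sampled at the transformed locations.

Choices that the source material leaves open, and how they were fixed:

* **Contour detection** — Otsu thresholding with a largest-component rule:
  robust and parameter-light; every threshold is config-exposed.
* **Crossline detection** — a line is flagged when its orthogonal-direction
  intensity sum deviates from the median of its neighbor window by more
  than `k = 5` robust (MAD) SDs *and* is a single-line spike: the local
  maximum of the absolute second difference of line sums, itself above `k`
  robust SDs. The spike condition separates one-line artifacts from
  anatomy, whose line-sum structure is several lines wide; without it the
  inter-ventricular column ridge of the phantom triggers false positives.
* **Artifact exclusion during registration** — reference-frame artifact
  lines are removed from the ROI; moving-frame artifact lines are excluded
  *pairwise inside the similarity*: any sample whose transformed location
  falls on a flagged line is dropped, whatever the candidate transform.
  Removing the lines from the ROI alone cannot help once the motion is
  comparable to the line width, because the samples land on the artifact
  after transformation.
* **Optimizer** — three-level exhaustive grid search (range +/-10 mm,
  +/-5 degrees; coarse step 2.5; refinement x5 per level; final step
  0.1 mm / 0.1 degree), bilinear interpolation, rotation about the step-3
  centroid. Exhaustive search is oracle-verifiable: a plain-R independent
  implementation reproduces it exactly at matched resolution. Ties resolve
  toward the smallest transform (lexicographic |theta|, |dx|+|dy|) for
  determinism. An optimum on the level-1 boundary raises a truncation flag.
* **Pre-blur** — both frames receive a symmetric Gaussian blur of 0.8 px
  before scoring. Rasterized piecewise-constant images otherwise bias
  sub-degree rotation estimates by up to ~0.3 degrees (the correlation
  surface of a crisp reference against a resampled moving frame peaks off
  the true angle); the symmetric blur removes most of that bias and leaves
  recovery of larger motions exact to the grid. Set
  `search_config(smooth_sigma_px = 0)` for raw scoring.
* **Reference frame** — every frame is registered to the first frame of the
  session, not to a rolling reference; slow drifts (e.g. in pitch) are
  thereby reported, not corrected or hidden.

`planes_to_6dof()` maps the per-plane estimates to patient axes: axial
supplies (lateral, AP, yaw), sagittal (AP, SI, pitch), coronal (lateral,
SI, roll). Each translation is seen by two planes; the default reconciles
the redundancy by arithmetic mean (`mode = "both"` keeps the per-plane
readouts). `summarize_motion()` reports the maximum absolute excursion
from the first-frame baseline per DOF per labeled window; `gate_check()`
turns the beam off when any target pixel leaves the gating boundary
(configurable excursion fraction, default 0).

On the default phantom at 1.3 mm pixels the tracker's static-sequence noise
floor is below 0.2 mm / 0.2 degrees at channel noise 4, noiseless applied
motions up to 5 mm / 5 degrees are recovered to half a pixel and 0.1
degree, and a programmed 0.9 mm step is clearly separated from the noise
floor — the property the tests assert instead of the unavailable volunteer
traces.

## MR image-quality metrics

`snr()` implements `mean x 0.66 / noise SD` with the noise SD measured in a
background (air) ROI by default; the 0.66 is applied as printed whatever
the ROI placement (a config decision, since the measurement context is not
fully specified). `percent_uniformity()` and `piu()` share the functional
form `100 x (1 - (max - min)/(max + min))`; `ghosting_ratio()` is
`|((top + bottom) - (left + right)) / (2 x large ROI)|`. Report rounding
follows the printed tables: PIU one decimal, ghosting three, percent dose
differences two; every function takes `digits = NA` for the raw value.

Low-contrast object detectability counts spokes whose three circles are all
"discernible". Discernibility is a human judgment; the automated surrogate
scores a circle when its mean exceeds the local annulus background by at
least `k = 3` background SDs, and is documented as a surrogate — human
counts enter `full_lcod_score()` directly, which just sums slices 8-11.
Geometric lengths are full-width-at-half-maximum distances between opposing
edges along central profiles (three-profile average), with sub-pixel linear
interpolation of the half-maximum crossings. The spatial-resolution insert
is read by a human; the report carries the value, it is not computed.

## Dosimetry arithmetic

Hounsfield-unit statistics of contoured immobilization structures are
reported as mean +/- SD (max). Dose comparisons use the calculated dose as
the reference denominator: `percent_dose_difference()` is
`100 x (measured - calculated)/calculated` and `tps_attenuation()` is
`100 x (NOC - ALL)/ALL`, where ALL models the full setup and NOC models
neither overlay nor coils — the only denominator convention that reproduces
the printed attenuation column from the printed doses. The
measured-vs-calculated percent columns of the source table do not recompute
exactly from the rounded printed doses, so they are displayed but never
used as test oracles. `attenuation_report()` flags rows whose
measured-vs-ALL difference exceeds a 2% action level (default).

## 3D setup registration

`rigid_register_3d()` maximizes histogram-based mutual information between
fixed-image ROI samples and the moving volume sampled trilinearly at
transformed locations. Numerical choices:

* **Binning** — 32 bins per axis by default, shrunk to
  `sqrt(n_points / 8)` when the ROI is small: with few samples a wide
  joint histogram rewards misalignments that merely spread the joint
  distribution (small-sample MI bias).
* **Pre-smoothing schedule** — interpolated noise creates grid-aligned
  local MI maxima. The volumes are box-blurred 3x at the coarse search
  levels and progressively unsmoothed (3, 3, 1, 1, 0 passes) as the
  coordinate-descent step shrinks from 3 mm/deg to 0.05 mm/deg, so the
  basin is smooth early and weakly determined rotations (roll, for a head
  that is nearly circular in the lateral-SI plane) keep their
  high-frequency information late.
* **Initialization and search** — translation starts at the foreground
  center-of-mass offset; then cyclic coordinate descent over the six DOFs
  with +/-1 and +/-2 step candidates per visit, within +/-15 mm / +/-8
  degrees. Deterministic throughout; a boundary optimum raises a
  truncation warning and a near-zero final MI is reported as a
  registration failure.

On synthetic repeat setups (fresh noise per scan), randomly drawn
transforms up to 10 mm / 5 degrees are recovered within 0.5 mm / 0.5
degrees in at least 95% of seeded draws, and forward/reverse registrations
compose to identity within twice that tolerance.
`pairwise_setup_variability()` registers every later scan to every earlier
scan (2-1, 3-1, 3-2 for three sessions) and pools the *absolute* per-DOF
changes into average/SD/min/max — the shape of an inter-fraction
variability table; absolute values are used because setup error magnitude,
not signed direction, is the quantity of interest.

## Problem sizes in the test suite

The suite validates on phantoms sized for exactness rather than realism:
120-160 px slices, 8-50 frame sequences, 64 x 64 x 48 volumes, 20-draw
property checks. These sizes were chosen so that every oracle (exhaustive
search, analytic geometry, hand arithmetic) can be computed exactly; the
algorithms have no dimension-specific constants, and the configuration
objects expose every range, step and threshold for full-scale use.

## Known limitations

* Trilinear/bilinear resampling cannot represent the phantom's ideal
  step edges: round-trip transform tests hold to 2% of dynamic range away
  from tissue interfaces, but pointwise errors at an unresolved edge are
  interpolation-limited, not algorithm-limited.
* Tracking assumes the anatomy stays in plane; through-plane motion
  appears as intensity change and will degrade the similarity rather than
  be estimated.
* The crossline model (constant multiplicative line) and the
  discernibility surrogate are stated stand-ins for effects the source
  material does not characterize quantitatively.
* DICOM support is a minimal reader/writer for uncompressed explicit-VR
  little-endian single-frame files — enough for scanner exports of that
  flavor and for synthetic fixtures; compressed syntaxes and sequences are
  out of scope.
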