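---
title: "Detecting the 3D limbus and the white-to-white boundary: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the 3D limbus and the white-to-white boundary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbus3d)
```

## The two measurements and why they differ

An eye-surface profilometer records the anterior surface of the eye — the
cornea and a surrounding band of sclera — as a cloud of (x, y, z) points in
millimetres, together with the apex coordinates and a calibrated grayscale
photograph. Two distinct boundaries live in those data. The **limbus** is
a geometric property of the *surface*: the ring where corneal curvature
gives way to the flatter scleral curvature. The **white-to-white (WTW)**
boundary is a property of the *image*: the visible edge between the dark
iris and the bright sclera. The iris lies in a different plane behind the
limbus, so the two contours differ by roughly 1–2 mm of radius; `limbus3d`
measures both, each from its natural data source, and quantifies the gap
as a per-degree map δ(θ).

## Limbus model

All analyses run in an apex-centred frame: +Z toward the camera, surface
stored with z ≤ 0, and sagittal height s(r) = −z along each meridian
(polar angle θ counter-clockwise from +X). On a meridian the slope ds/dr
is zero at the apex, grows to a local maximum just before the limbus,
decreases through the limbal transition, and grows again on the sclera.
Equivalently, the second radial derivative d²s/dr² has an interior local
minimum at the limbus. The detector does exactly this:

1. **Polar resampling** (`polar_resample`). Scattered points are
   rasterized to a regular XY grid by a per-node moving-least-squares
   plane fit over a 3×3-cell neighbourhood (exact on planes, O(h²) bias on
   smooth surfaces, `NA` where a node has no support), then sag is sampled
   bilinearly on 360 meridians at radial step `dr` = 0.01 mm out to
   8.5 mm. No installed interpolator handles scattered 2-D data, so this
   stage is implemented in the package and is deliberately simple enough
   to verify against closed-form surfaces (sphere, paraboloid) in the
   tests.
2. **Derivatives** (`meridian_derivatives`). A Savitzky–Golay local cubic
   is fitted over a sliding window and d1/d2 evaluated analytically from
   the fitted coefficients — exact on polynomials up to the fit order, one
   fewer tolerance than differencing pre-smoothed data. Invalid gaps split
   the meridian into runs filtered independently; runs shorter than the
   window stay invalid.
3. **Turning point** (`locate_limbus_point`). Within the search window the
   most prominent interior local minimum of d2 is the limbus; its
   topographic prominence is the per-meridian quality score, a three-point
   parabolic fit refines the position below the grid step, and prominence
   ties break toward smaller radius (the corneal side, conservative
   against scleral artefacts). No interior minimum, or insufficient valid
   data, yields an *invalid flag*, never an error — the per-meridian
   independence is what lets eyelid-occluded scans through.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_meridians` | 360 | — | 1° angular resolution, matches the contour containers |
| `dr` | 0.01 | mm | radial step; detection is refined below it parabolically |
| `window` | 4.5–8.5 | mm | brackets clinically reported limbal radii (~5.8–7.0 mm) with margin |
| `smooth_halfwidth` | 0.7 | mm | about 2× the width of the limbal curvature transition; see below |
| `poly_order` | 3 | — | lowest order giving an unbiased local second derivative |
| `min_prominence` | 0.02 | 1/mm | rejects ripple minima while passing any realistic limbal dip |
| `spacing` | 0.05 | mm | raster cell, of the order of profilometer point spacing |

The smoothing half-width deserves its own note. The second derivative of a
noisy signal is the quantity most sensitive to the window choice: with
5 µm height noise a 0.25 mm half-width leaves d² noise of ≈ 0.08 /mm —
the same order as the limbal dip itself — and per-meridian radius errors
above 0.1 mm. The limbal transition in the model (and clinically) is a
feature several tenths of a millimetre wide, so the efficient window is of
that scale, not of the grid scale: at 0.7 mm the same noise yields mean
radius errors near 0.03 mm while noiseless recovery stays exact to the
grid. Widening much beyond the transition width would start to blur the
dip into the scleral curvature change, biasing the minimum outward.

## White-to-white model

Pixels of a grayscale eye image cluster into three populations — pupil,
iris, sclera, in that intensity order regardless of iris colour or
lighting. A fixed threshold cannot follow lamp brightness or camera gain,
so the cut is chosen per image: the light-intensity frequency spectrum is
smoothed by a 7-level moving average (mass-preserving, reflective ends),
its three most prominent local maxima are identified (boundary modes at 0
and 255 count; peaks are reported at the raw-count mode when smoothing
flattens a spike into a plateau) and sorted by *intensity* into
(pupil, iris, sclera); the threshold is the valley of the smoothed
spectrum between the iris and sclera peaks. The dark class is opened with
a 3-px disc (breaking pixel bridges to lashes), the connected component
containing the seed (default: image centre) is kept, and interior holes —
the pupil and the device's two specular highlight dots — are filled. Rays
cast from the mask centroid, one per degree with the horizontal/vertical
millimetre calibrations applied anisotropically, give the WTW radius
profile; NT and SI distances are sums of opposite-ray radii.

Peak prominence is thresholded at 1% of the spectrum maximum: large
enough to sit far above counting noise on a megapixel histogram (~0.3%),
small enough to keep a small dark pupil visible against a dominant
scleral peak.

## Contour geometry

The limbus contour is fitted by ordinary least squares in z,
z = a·x + b·y + c; at limbal tilts of a few degrees this is
indistinguishable from a total-least-squares fit (the difference scales
with 1 − cos of the tilt) and is verifiable by hand. Tilt angles are
θy = atan(a) and θx = atan(b) in degrees; mirroring a right eye to a left
eye (x → −x) flips the sign of θy and preserves θx, which is how
opposite-signed between-eye tilts are expressed. `level_contour` applies
the minimal rigid rotation taking the fitted normal to +Z; for planar
contours the leveled z is constant to machine precision, for non-planar
contours the residual is preserved up to that same cos-of-tilt factor.

Sagittal depths are taken on the *raw* (unleveled) contour, as |z| of the
point on each clinical meridian relative to the apex plane — leveling
first would partially remove exactly the side-to-side depth differences
the measurement is after. Nasal/temporal labels resolve through
laterality: superior = 90° and inferior = 270° for both eyes, nasal =
180° for right eyes and 0° for left eyes (the camera faces the patient).

δ(θ) subtracts the WTW radius from the XY-projected limbus radius about a
common origin, per integer degree. The origin is the apex by default, with
the WTW centroid as an alternative (`origin_policy`), since the natural
choice depends on how a clinic would anchor the map; both are exposed and
the tests pin the behaviour of each. Angular resampling interpolates only
across gaps of ≤ 3°, so invalid meridians propagate rather than being
bridged silently.

## Statistics

Cohort cells are summarized as mean ± sample SD and min : max. The
two-sample test is Student's pooled-variance t (df = n₁ + n₂ − 2,
two-sided p), the classical default in the clinical literature of the
instrument's era; Welch's form is available by flag. Zero-variance
degenerate inputs resolve by the limits (equal constant samples: t = 0,
p = 1). Pairing of fellow eyes is deliberately ignored to match the
two-sample design.

## What the synthetic generator does and does not emulate

`surface_truth`/`make_surface` build surfaces whose radial curvature
profile is corneal (1/7.8 mm⁻¹ by default) out to the limbus, dips by a
Gaussian of amplitude 0.3 /mm and width σ = 0.35 mm centred at the
prescribed ring radius, and relaxes to scleral curvature (1/12 mm⁻¹)
starting 3σ beyond the ring — so the analytic d² minimum is *exactly* at
the prescribed radius and the truth never depends on the detector. Sag is
integrated in closed form (polynomial smoothstep integrals plus error
functions), tilt is imposed as the minimal rigid rotation that makes the
truth ring's fitted plane have exactly the prescribed (θx, θy), the
surface is re-centred on its numerically located post-tilt apex, and
optional Gaussian height noise and eyelid sectors are applied last. A
hard two-sphere junction was rejected as the generator model because a
literal sphere-to-sphere join has no interior d² minimum to serve as
ground truth.

`image_truth`/`make_eye_image` render a pupil disc (125 px ≈ 5 mm
diameter — a darkened-room, dilated pupil, as the scanning protocol
requires), an iris ellipse and a scleral background at three mean
intensities with Gaussian pixel noise, plus optional highlight dots; the
per-degree WTW truth is the analytic ellipse radius in millimetres.

Passing recovery tests on these fixtures shows the estimators are
correct and noise-efficient *under the model*: a smooth axisymmetric
curvature transition, stationary Gaussian noise, three well-separated
intensity populations. Real scans add tear-film and fluorescein artefacts,
non-Gaussian outliers near lashes, limbal width asymmetry, iris texture
and shadows — none of which the generator produces, so field performance
must be established on instrument data; what the suite does guarantee is
that failures there would come from the data model, not the numerics.

## Numerical choices and degenerate inputs

- Raster nodes need ≥ 3 supporting points and a non-singular normal
  system, else `NA`; polar samples touching an `NA` node are invalid.
- The apex sample is pinned to s = 0 by subtracting the interpolated
  origin value (a common offset across meridians).
- Prominence of a histogram/d² extremum is standard topographic
  prominence; plateau extrema report their first sample (smaller index /
  smaller radius).
- `two_sample_t` handles the zero-variance limit explicitly because the
  underlying t machinery refuses constant data.
- MAT containers: only numeric/char arrays are parsed (vendor exports are
  flat), with an explicit error for structs/cells/complex; field names go
  through a user key map because vendor names are not standardized, and
  laterality is *never* guessed.
- All randomness flows through explicit seeds recorded in truth records;
  repeated scans of an eye are processed independently, never averaged
  inside the detectors.

## Problem sizes used in the checks

Recovery checks run on full-size problems — 360 meridians at dr = 0.01 mm
(851 radial samples), ~116k surface points at 0.05 mm spacing, 1024×1280
images — once or a few times per property; distributional checks (null
uniformity of p) use 2000 replications of n = 15 samples. Each full
surface pipeline takes a few seconds on one CPU.

## Known limitations

- The raster/bilinear stage assumes point support dense relative to the
  0.05 mm cell; very sparse scans degrade to invalid regions rather than
  degrading accuracy silently, but cell size is a fixed parameter, not
  adaptive.
- OLS plane fitting and vertical (z) residuals are approximations valid
  at small tilts; beyond ~10° the cos-of-tilt discrepancies stop being
  negligible.
- The image-to-surface registration assumes the principal point maps to
  the surface origin with axes aligned — adequate for δ maps at the
  reported scale, but a device-specific calibration would supersede it.
- Limbus *width* is not estimated; the contour is the single turning
  point per meridian.
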