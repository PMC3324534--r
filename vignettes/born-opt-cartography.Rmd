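---
title: "Born-normalized OPT cartography of the mouse heart: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Born-normalized OPT cartography of the mouse heart: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optheart)
```

This vignette is the package's account of the science it implements: the
physical model behind each stage, the assumptions those stages make, the
tunable parameters and their defaults, and the numerical and design
choices taken where more than one reasonable option existed. It states no
empirical result that the package's tests do not themselves compute.

## 1. Imaging model

### Geometry

Optical projection tomography of a cleared specimen is treated as
parallel-beam CT: the sample rotates about a vertical axis (the z axis of
all volumes), a telecentric detection path collects rays parallel to the
optical axis, and each detector row corresponds to one reconstructed
axial slice. The forward model (`forward_project()`) therefore contains
no cone-beam or magnification terms. Voxels are isotropic; world
coordinates are mm with the origin at the volume center.

### Transmission channel

Frames follow Beer–Lambert attenuation of the unobstructed source
intensity `I0` along each ray,

$$ I = I_0 \exp\!\Big(-\int \mu \, dl\Big), $$

so `-log(I/I0)` (`transmission_to_absorbance()`) lives in the Radon
domain of the attenuation coefficient $\mu$ (units 1/mm) and is inverted
slice by slice with filtered backprojection.

### Fluorescence channel and the Born ratio

Cleared tissue is treated as absorbing but non-scattering: a single-
scatter model in which collimated excitation light is attenuated along
the illumination path up to a fluorophore, and the emission is attenuated
along the detection path from the fluorophore to the detector. When
excitation and emission are attenuated by the same map (the per-channel
pairing used throughout: each fluorescence channel is normalized by the
transmission image at its own excitation wavelength), the two path
integrals along a transillumination ray sum to the full chord through the
sample, which is exactly what the transmission frame measures. The
pixelwise Born ratio

$$ n = \frac{F}{T + \varepsilon} \approx \frac{1}{I_0}\int c_f \, dl $$

therefore cancels the heterogeneous absorption ray by ray, leaving (up to
the known factor $I_0$) the Radon transform of the fluorophore density
$c_f$, which FBP inverts quantitatively. The package also implements the
general two-wavelength path-integral model (`absorption_em`); with equal
maps it reduces exactly to the fast chord form, and a test asserts that
equality.

Assumptions worth keeping in mind: no scattering (valid for solvent-
cleared hearts, not for uncleared tissue), monochromatic per-channel
attenuation, and a detection path collinear with the illumination. The
regularizer $\varepsilon$ defaults to $10^{-3} I_0$; it only matters for
rays whose transmission approaches zero.

## 2. Sinogram corrections

The correction order is fixed and enforced by the pipeline: **power
equalization, then ring correction, then denoising**, all in the
intensity domain before any log or ratio transform.

* `power_equalize()` removes per-angle source-power fluctuations
  (vertical sinogram stripes) by rescaling each angle so its mean over a
  sample-free reference margin — by default the outermost 10% of detector
  bins per side — matches the global reference mean. The global scale is
  intentionally left unidentified (it cancels in the Born ratio and in
  all ratio maps). Fluorescence sinograms reuse the factors estimated
  from their paired transmission sinogram: the fluorescence margin is
  dark and carries no power information, while the transmission margin
  directly sees the source.
* `ring_correct()` estimates a fixed multiplicative gain per detector
  bin as the ratio of the bin's mean over angles to a smoothed baseline.
  The baseline is a running median rather than the moving average one
  might first reach for: the running median is exact on monotone
  stretches of the clean profile (no blurring at the sample edge, where a
  moving average manufactures spurious gains an order of magnitude above
  the stated 0.5% idempotence bound), and it rejects isolated bad bins.
  Because a median baseline still underestimates an isolated spike by
  the local profile slope, bins flagged as clear outliers (deviation
  beyond 5 robust SDs, at least 0.5%) get a second-stage baseline
  interpolated from the unflagged bins, which is slope-unbiased. A single
  5% column-gain spike is suppressed more than tenfold in the
  reconstruction (tested). In the full pipeline the gains are estimated
  on the transmission channel and applied to the paired fluorescence
  channel: the column gain is a property of the shared detector, and
  estimating it on a fluorescence sinogram would flatten genuine probe
  features that sit on the same detector bins at every angle (a centered
  inclusion is the worst case; this failure mode was observed and is the
  reason for the design).
* `denoise()` offers a 2D median filter (default radius 1; EBImage's
  constant-time implementation, with an exact monotone rescale to its
  required unit range) and a reduced block-matching collaborative filter:
  groups of similar patches are jointly DCT-transformed (2D within
  patches, 1D across the group), hard-thresholded at 2.7 times the noise
  SD (estimated from the median-filter residual when not given), inverted
  and aggregated with sparsity weights. This captures the essential
  mechanism of BM3D-class denoisers at a fraction of their complexity;
  exact published parameters for this application do not exist.

## 3. Filtered backprojection

`fbp_slice()` zero-pads each projection to the next power of two (at
least twice the detector width), applies a frequency-domain ramp filter
(`ram-lak`), optionally windowed (`shepp-logan`, the default, or
`hann`), and backprojects with linear interpolation. The angular
quadrature weight is $\Delta\theta/2$; full-turn (360°) acquisitions
cover every projection direction twice and receive an extra factor 1/2.
Output values are per-mm physical units (the detector bin pitch is the
voxel size). The implementation is validated against an independent
brute-force oracle (explicit DFT-matrix filtering, per-pixel loops) to a
relative RMS below $10^{-6}$, and against the Beer–Lambert closed form of
a uniform disk (plateau within 5%).

## 4. The left-ventricle model

The LV is modeled as a thick-walled prolate ellipsoid ($a = b < c$)
truncated at a base plane. The long axis is fitted first
(`fit_long_axis()`): starting from the principal direction of the voxel
coordinates, the fit iterates a weighted least-squares line through
per-slice centroids with slices taken *perpendicular to the current
axis*. The iteration matters: slicing a tilted ellipsoid along a grid
axis traces a conjugate diameter, not the symmetry axis, and a single
pass can be off by tens of degrees where the iterated fit is within a
fraction of a degree (tested at a 30° tilt).

`fit_lv_ellipsoid()` then extracts epicardial surface voxels as the
6-connectivity erosion difference of the filled mask, drops the flat
base-cut facet (the long-axis end whose terminal cross-section is
larger), and fits a coaxial ellipsoid: a linear least-squares solve of
the algebraic form $A(x^2{+}y^2) + Bz^2 + Cx + Dy + Ez = 1$, followed by
Nelder–Mead refinement of center and semi-axes on normalized radial
residuals (tolerance $10^{-8}$, at most 200 iterations), with two rounds
of robust trimming (drop residuals beyond 3 MADs, refit). The trimming is
what keeps jittered base-cut remnants from biasing the long semi-axis
(untrimmed, a 1-voxel boundary jitter produced a −12% bias on $c$).
Finally half a voxel is added to the semi-axes, since boundary voxel
*centers* lie inside the continuous surface by half a voxel on average.
Across 20 seeded phantoms with random tilt, offset and boundary jitter,
semi-axis RMSE is under 5% with bias under 2% (tested).

The prolate frame uses $\mu = 0$ at the **apex** pole, and the base
truncation retains `truncation_fraction` (default 3/4) of the long-axis
*extent* $2c$ from the apex, i.e. the cut plane sits at
$z_{\text{local}} = c(1 - 2\,\mathrm{tf}) = -c/2$ for the default. On the
reference surface this corresponds to $\mu_{\text{trunc}} =
\arccos(1 - 2\,\mathrm{tf}) = 2\pi/3$. Everything basal of that line is
displayed but excluded from every quantitative summary. The inverse
coordinate map is evaluated through the conformal identity $z + i\rho =
f \cosh(\lambda + i\mu)$, which round-trips random points to better than
$10^{-9}$ relative error; on-axis points have undefined azimuth and are
flagged rather than silently assigned. A fitted ellipsoid within 1% of
spherical is flagged `oblate_degenerate` (the focal distance, and with it
the whole prolate frame, is numerically meaningless there).

## 5. Cartography

`sample_shells()` interpolates a volume trilinearly on `n_shells`
constant-$\lambda$ ellipsoids spanning the wall; because a confocal
family cannot follow both surfaces of a non-confocal wall exactly, the
default range matches the epicardial surface exactly and the endocardial
equator approximately. `total_projection()` sums the shells per node (the
paper-style "2D total projection"). For thickness normalization the sum
is first multiplied by the per-node radial step (shell span / shell
count), turning it into a radial line integral, and then divided by the
local `wall_thickness()`; for a uniform field this quotient is constant
regardless of how much myocardium the ray traverses, which is the point
of the normalization (tested on a wall whose thickness varies by more
than 30%). A plain sum divided by thickness would *not* have that
property, because the shell count per node is fixed.

`wall_thickness()` marches outward in $\lambda$ and takes the distance
between the last exits from the filled endo- and epicardial masks;
missing crossings mark the node invalid rather than zero, so holes are
distinguishable from thin wall.

The Bull's-Eye rendering maps radius linearly in $\mu$ (apex at center,
truncation line at the rim) so the disk area element matches
$\mu\,d\mu\,d\theta$ and area-weighted totals are preserved under
re-gridding (within 2%, tested). The AHA 17-segment partition splits the
retained $\mu$ range into three equal rings — basal (segments 1–6, 60°
sectors), mid-cavity (7–12), apical (13–16, 90° sectors rotated 45° per
convention) — with the apical cap (17) as the inner half of the apical
ring. The $\mu$ cut points are this package's convention (recorded in the
label attributes); the AHA statement fixes the segment count and
ordering, not the cut points on an ellipsoid. The anterior wall sits at
$\theta = 0$ by default with a configurable offset.

Probe-ratio maps are classified per node against thresholds 1.1 and 0.9
(the Ly6C-hi/Ly6C-lo reading of the protease/phagocyte ratio): above 1.1
"high", 0.9–1.1 "intermediate", and — for completeness of the partition —
below 0.9 "low"; nodes whose denominator falls below a floor are
"undefined" and excluded from area statistics. Classification is
scale-invariant by construction.

Infarct delineation thresholds the myocardial bead intensities (Otsu by
default, or a fraction of the median), closes the result morphologically
(radius 2 voxels) and keeps the largest 6-connected component. A uniform
bead field returns an empty, flagged mask; an all-zero bead volume is an
error. Distance-band densities use an exact Euclidean distance transform
(separable parabolic-envelope passes) from the infarct, restricted to
myocardium outside it; the remote fraction is the share of total
myocardial signal outside every band.

## 6. Colocalization

The coefficient is the Manders-type overlap
$r = \sum v_1 v_2 / \sqrt{\sum v_1^2 \sum v_2^2}$, not Pearson
correlation: for nonnegative signals it is exactly 1 under
proportionality and exactly 0 for disjoint supports, the two limits the
CCF is meant to report, whereas Pearson can go negative. The reported
shift is the displacement applied to the second volume that maximizes its
overlap with the first; $r$ is evaluated on the overlap region only, and
shifts overlapping less than 25% of the volume are masked out. Rotational
profiles take the translations-first shortcut: the second volume is first
displaced by the translational argmax, then rotated about the model
center around each principal axis. This is deliberately suboptimal (a
joint 6-DOF search is not attempted); for patterns where a translation
can partially absorb a rotation the rotational peak is correspondingly
biased, which the tests demonstrate and work around with a symmetric
two-blob pattern. FWHM is read off the 1D profile through the argmax with
linear interpolation at half maximum (baseline 0); profiles that never
fall below half maximum within the explored range return the span,
flagged as a lower bound.

## 7. The synthetic phantom and what passing tests show

`make_lv_phantom()` builds the study conditions: a thick-walled truncated
ellipsoid LV (defaults: epicardial semi-axes 3.0 × 3.0 × 4.6 mm,
endocardial 2.2 × 2.2 × 3.8 mm, 0.12 mm voxels on a 96³ grid — a mouse
heart at realistic OPT sampling), an apical-lateral infarct wedge, two
probe fields with smooth distance-transform halos around the infarct
(default peri-infarct/remote contrast 4, halo length 1.5 mm; the second
probe slightly wider and weaker so the channels are correlated but not
identical), a homogeneous bead field that is zero inside the infarct, and
an absorption map (myocardium 0.25/mm, background 0.01/mm, cavity
0.02/mm — attenuation of cleared tissue in the NIR, giving chord
attenuations around $e^{-1}$). A piecewise-constant `"bands"` probe
profile (contrast at distances below 3.5 mm, baseline beyond) exists so
distance-band quantification has an exactly known target. Instrument
artifacts are injected separately: log-normal per-angle source factors,
fixed per-column detector gains, Gaussian or Poisson noise, all under one
seed.

What the phantom does *not* emulate: scattering, wavelength-dependent
attenuation within a channel, refractive-index mismatch at the sample
boundary, detector nonlinearity and drift (only a static gain), partial-
volume effects of real segmentations, and anatomical departures from the
ellipsoid (papillary muscles, trabeculation, right ventricle). Passing
tests therefore demonstrate the correctness of the *algorithms* under the
stated physics, not instrument-level accuracy on real hearts.

Default angular sampling is 360 angles over 360° (fluorescence needs the
full turn in general; absorption is complete over 180°). Tests and the
worked examples run scaled down — 48³–128³ grids, 90–180 angles, shells
and map grids a few dozen nodes wide — sizes chosen so the whole suite
exercises every stage end to end in about a minute while leaving each
quantitative bound (5% FBP plateau, 5% fit RMSE, 10× ring suppression,
10% band-ratio recovery) comfortably determined by method error rather
than sampling noise.

## 8. Known limitations

* The Born cancellation is exact only in the collinear transillumination
  geometry with per-channel wavelength pairing; oblique collection or
  strong emission/excitation spectral separation would leave residual
  absorption bias.
* The confocal shell family approximates the endocardial surface; shell
  coverage near the apex of a thick wall is the weakest point of the
  cartography (visible as the tolerance in the thickness-normalization
  test).
* `ring_correct()` cannot distinguish a genuine feature that stays on one
  detector bin at *every* angle from a gain error on that bin when it
  only sees a single sinogram; the pipeline avoids the ambiguity by
  estimating gains on the transmission channel.
* The EDT-based distance bands use straight-line distance, not geodesic
  distance within the myocardium; bands can leak across the cavity for
  extreme geometries.
* TIFF output is min–max normalized 32-bit float with the affine scale in
  a YAML sidecar, because the underlying TIFF library only guarantees the
  unit interval; readers must keep the sidecar next to the stack.
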