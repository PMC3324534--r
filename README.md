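# optheart

Born-normalized optical projection tomography (OPT) cartography of the
mouse heart, in R.

## The problem

Optical projection tomography images whole optically cleared specimens the
way CT images patients: the sample rotates in front of a collimated light
source, a telecentric lens collects parallel-ray transillumination frames,
and filtered backprojection (FBP) inverts the resulting sinograms. For a
cleared (low-scattering) but strongly and *heterogeneously* absorbing organ
such as an infarcted heart, raw fluorescence projections cannot be
reconstructed directly: both the excitation light on its way to a
fluorophore and the emitted light on its way to the detector are partially
absorbed, so deep structures (papillary muscles, septum) appear dimmer than
they are. The Born-ratio normalization divides each fluorescence frame by
the co-registered transmission frame at the excitation wavelength,

```
n(t, z, theta) = F(t, z, theta) / (T(t, z, theta) + eps),
```

which cancels the absorption term ray by ray; FBP of the normalized stack
then recovers a quantitative fluorophore distribution. On top of the
reconstruction, the package maps molecular-probe distributions over the
left ventricle (LV), modeled as a thick-walled truncated ellipsoid in
prolate spheroidal coordinates `(lambda, mu, theta)`,

```
x = f sinh(lambda) sin(mu) cos(theta)
y = f sinh(lambda) sin(mu) sin(theta)      f = sqrt(c^2 - a^2)
z = f cosh(lambda) cos(mu)
```

with `mu = 0` at the apex, and renders cylindrical and AHA 17-segment
Bull's-Eye maps, classifies dual-probe ratio maps (thresholds 1.1 / 0.9),
delineates the infarct from a perfusion-bead channel, quantifies probe
density in distance bands around the infarct, and measures dual-probe
colocalization with the cross-correlation function

```
r = sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
```

over relative translations and rotations, summarized by its full width at
half maximum.

The intended users are cardiovascular imaging groups who need a desk-scale,
fully testable implementation of this analysis chain: every stage can be
exercised against a synthetic LV phantom with known ground truth, so no
instrument or deposited data set is required.

## What is in the package

| Stage | Functions |
|---|---|
| Synthetic hearts + forward model | `make_lv_phantom()`, `forward_project()`, `inject_artifacts()` |
| Sinogram corrections | `power_equalize()`, `ring_correct()`, `denoise()` |
| Reconstruction | `transmission_to_absorbance()`, `born_normalize()`, `fbp_slice()`, `reconstruct_volume()` |
| LV model | `fit_long_axis()`, `fit_lv_ellipsoid()`, `prolate_to_cartesian()`, `cartesian_to_prolate()`, `wall_thickness()` |
| Cartography | `sample_shells()`, `total_projection()`, `bulls_eye()`, `aha17_labels()`, `ratio_classify()`, `infarct_mask_from_beads()`, `distance_band_density()` |
| Colocalization | `overlap_coefficient()`, `ccf_translational()`, `ccf_rotational()`, `ccf_fwhm()` |
| Orchestration / I/O | `opt_config()`, `run_pipeline()`, `read_projection_stack()`, `write_outputs()` |

A thin command-line wrapper with verbs `phantom`, `reconstruct`, `map`,
`coloc` and `run` is installed at `inst/cli/optheart`.

## Worked example

```r
library(optheart)
cfg <- opt_config(
  phantom   = list(grid_shape = c(64L, 64L, 64L), voxel_size = 0.18),
  angles    = list(n = 180L, span_deg = 360),
  artifacts = list(source_fluctuation_sd = 0.05, detector_gain_sd = 0.01,
                   noise_model = "gaussian", noise_scale = 0.002),
  map       = list(n_mu = 36L, n_theta = 72L, n_shells = 6L),
  coloc     = list(max_shift = 3L, angles_deg = seq(-10, 10, 5)))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result>
#>   volumes: absorption, probe_a, probe_b, beads
#>   maps:    thickness, probe_a_cyl, probe_a_bullseye, probe_b_cyl, ...
#>   AHA segments: 17
#>   CCF max r = 0.994 at shift (0, 0, 0)
#>   peri/remote band density ratio = 2.32, remote fraction = 0.31
print(res$model)
#> <lv_ellipsoid>
#>   center      (-0.000, 0.000, -0.003) mm
#>   semi-axes   a = b = 3.011, c = 4.618 mm
#>   focal dist  f = 3.501 mm
#>   truncation  75% of long axis retained from apex
```

Reading the output: the simulated heart (epicardial semi-axes 3.0 x 3.0 x
4.6 mm) is recovered by the ellipsoid fit to within half a voxel; the two
probe channels, which the phantom concentrates around the same infarct,
colocalize with overlap coefficient 0.994 peaking at zero relative shift;
the Bull's-Eye segmentation produces the standard 17 AHA segments; and the
probe density 1-3 mm from the infarct boundary is about 2.3 times the
density at 4-6 mm (the phantom's smooth peri-infarct halo), with 31% of
the myocardial signal lying beyond both bands. `write_outputs(res, dir)`
writes the volumes (32-bit TIFF stacks), maps (TIFF + CSV), statistics
tables, configuration, provenance and log.

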