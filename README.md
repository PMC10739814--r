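# pgcam

Compton-camera imaging of boron neutron capture prompt gamma rays, in R.

Boron neutron capture therapy (BNCT) delivers dose through
^10^B(n,α)^7^Li. About 94% of captures leave the ^7^Li product excited, and
its de-excitation emits a 478 keV prompt gamma ray (PG) — so imaging the PG
emission maps the capture reaction, and hence the dose, directly. The
practical obstacles are the 511 keV annihilation line only 33 keV (~7%)
above the PG line, and an intense uncollimatable gamma background. A
Compton camera built from stacked Si scatterers and CdTe absorbers needs no
collimator and resolves the PG/AG pair spectroscopically: each two-hit
event with energies \(E_1\) (scatterer) and \(E_2\) (absorber) constrains
its source to a cone of half-angle

cos θ = 1 − m_e c² (1/E₂ − 1/(E₁+E₂)),  m_e c² = 511 keV.

`pgcam` implements the full analysis chain for such an experiment as a
tested pipeline, for medical-physics researchers studying PG imaging:

* **physics**: Compton kinematics, Klein–Nishina angle sampling, cone
  geometry (`kinematic_angle`, `sample_kn_angle`, `geometric_angle`);
* **camera**: energy/position/axis-tilt response calibrated to the
  instrument's 2.2% energy resolution and 5.4° angular resolution measure
  at 662 keV (`response_model`, `calibrate_angular_blur`, `arm`);
* **synthetic data**: seeded Monte-Carlo generation of list-mode two-hit
  events for the six preset bench scenes (B₄C target at three positions,
  graphite control, no target, underwater target), with ground-truth labels
  (`preset_scene`, `generate_listmode`);
* **selection**: the three two-hit selection rules — 468–488 keV sum
  window, E₁ < 200 keV, Cd X-ray band veto (`select_events`);
* **spectroscopy**: photopeak fits and the net/gross peak ratio with
  linear-sideband background (`fit_photopeak`, `net_gross_ratio`);
* **reconstruction**: Gaussian-weighted cone back-projection and list-mode
  MLEM on the target plane (`backproject`, `mlem`);
* **metrics**: background-image subtraction and the pixel-value-ratio
  contrast with negative clipping (`subtract_images`, `pvr`);
* **pipeline**: a config-driven end-to-end driver (`run_pipeline`).

## Worked example

```r
library(pgcam)

geometry <- camera_geometry()
response <- calibrate_angular_blur(geometry, response_model())

# closed-form anchors
b10_mass(100)                                   # 14.49841 g of 10B in 100 g B4C
equivalent_treatment_time(1e3, 1, 7200,         # bench run ...
                          1e9, 80, 100)         # ... = 0.9 s of clinical capture
angular_displacement(c(5, 6), 100)              # 8.748866 10.510424 mm at 100 mm

# simulate the B4C-at-X=-2cm scene, select, reconstruct
lm  <- generate_listmode(preset_scene("b4c_x-2"), geometry, response, seed = 77)
sel <- select_events(lm)
sel$report
#> Selection: 6086 of 176941 events kept
#>   rejected by energy window [468, 488] keV: 145258
#>   rejected by E1 >= 200 keV: 25572
#>   rejected by Cd X-ray band [20, 35] keV at (last Si, first CdTe): 25

img <- backproject(sel$selected, image_grid(), response)
image_argmax(img)
#>     x     y
#> -22.5   7.5        # the 50 mm-wide target is centred at (-20, 0) mm

pvr(img, target_roi(preset_scene("b4c_x-2"), image_grid()))
#> PVR = 1.12 (ROI mean 608.7 / outside mean 541.2, 0 pixels clipped)

bg  <- generate_listmode(preset_scene("no_target"), geometry, response, seed = 78)
sub <- subtract_images(img, backproject(select_events(bg)$selected,
                                        image_grid(), response))
pvr(sub, target_roi(preset_scene("b4c_x-2"), image_grid()))
#> PVR = 5.03 (ROI mean 156.4 / outside mean 31.11, 518 pixels clipped)
```

The selection keeps ~6100 of ~177k two-hit events (the measured runs used
5261–6267 events per 2 h scene); the back-projection peaks inside the
target footprint; and subtracting the no-target background image raises
the target contrast from 1.1 to 5.0.

The whole chain, including spectra, MLEM images, subtracted images, and the
net/gross and PVR tables, runs from one call:

```r
run_pipeline(list(scenes = c("b4c_x-2", "no_target"), exposure_s = 720,
                  seed = 1), out_dir = "runs/demo")
```

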