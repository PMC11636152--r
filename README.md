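# fencorr

Correlative morphometry of liver sinusoidal endothelial cell (LSEC)
fenestrations.

LSEC are perforated by fenestrations — open transcellular nanopores of
roughly 50–350 nm diameter, clustered in sieve plates — whose size and
number report on liver health and drug response. Because the pores sit at
or below the resolution limit of optical microscopy, they are measured
with a mix of modalities (SEM, SIM, STED, AFM), each with its own sample
preparation and its own bias: dehydration for SEM dilates pores by
30–40%, the optical point spread function (PSF) blurs "negative"
structures and shrinks their measured diameters, and the AFM tip can
mechanically dilate pores at higher load forces. `fencorr` implements the
full analysis chain needed to study these effects quantitatively, with a
synthetic ground truth so every stage is testable without microscope
data:

* **Simulation** (`generate_cell_model`, `apply_dehydration`,
  `render_sem`, `render_optical`, `render_qi`) — sieve plates of
  elliptical pores with Gaussian-distributed equivalent diameters
  `d = sqrt(a*b)`, micron-scale gaps, closed (invagination-only) pores;
  dehydration as a uniform axis dilation λ with extra radial elongation at
  plate edges; SEM-like crisp rendering, Gaussian-PSF + Poisson-noise
  optical rendering, and AFM Quantitative Imaging (QI) force-curve stacks
  with spherical-tip convolution and Hertz contact mechanics.
* **Segmentation** (`normalize_contrast`, `binarize`, `extract_pores`) —
  percentile contrast normalization, modality-aware thresholding
  (membrane/background levels for optics, Otsu for SEM, depth fraction
  for AFM topography), connected components, and per-pore area,
  equivalent diameter, ellipse axes and roundness (`d_min/d_max`).
* **QI processing** (`find_contact_point`, `reconstruct_topography`,
  `fit_hertz`, `elasticity_map`, `force_tomography`) — per-pixel
  force–distance curves; topography reconstructed at any load force up to
  the maximum, with cantilever-deflection correction; apparent Young's
  modulus by least-squares Hertz fits
  `F = (4/3)·E/(1−ν²)·√r·δ^{3/2}`; force tomography of pore diameters at
  increasing load.
* **Correlation** (`fit_transform`, `map_points`, `match_pores`) —
  landmark-based similarity/affine/projective registration and optimal
  one-to-one pore matching (gated Hungarian assignment).
* **Statistics** (`fit_diameter_distribution`, `roundness_stats`,
  `paired_regression`, `percent_change`, `correction_coefficient`,
  `porosity_frequency`, `build_report`) — Gaussian peak fits of diameter
  histograms ("mean at the peak"), paired wet/dry regressions, dilation
  percentages, the wet/dry correction coefficient, porosity and
  fenestration frequency.
* **Pipeline + IO** (`run_pipeline`, TIFF+JSON sidecars, CSV tables, a QI
  HDF5 container, YAML configs, and a CLI at `inst/cli/fencorr.R`).

## Worked example

Simulate a wet-fixed cell, dry it with a 34% diameter dilation, image
both states, and recover the dilation from the paired measurements:

```r
library(fencorr)

wet <- generate_cell_model(field_size = c(42000, 42000), n_plates = 4,
                           pores_per_plate = 500, min_separation = 100,
                           seed = 11)
dry <- apply_dehydration(wet, dehydration_params(lambda_dilation = 1.34,
                                                 edge_elongation = 1,
                                                 p_open_on_drying = 0))

wt <- segment_image(render_sem(wet, pixel_size = 10))
dt <- segment_image(render_sem(dry, pixel_size = 10))
mt <- match_pores(wt, dt, gate = 150)

fw <- fit_diameter_distribution(wt)   # wet peak
fd <- fit_diameter_distribution(dt)   # dry peak
percent_change(fw$mu, fd$mu)
#> [1] 34
paired_regression(mt, wt, dt, "d_eq")$slope
#> [1] 1.338161
paired_regression(mt, wt, dt, "area")$slope
#> [1] 1.794347
correction_coefficient(list(c(fw$mu, fd$mu)))$ratios_2dp
#> [1] 0.75
```

The fitted diameter slope recovers the simulated λ = 1.34, the area slope
its square (≈1.80), and the wet/dry peak ratio the 0.75 correction
coefficient that converts a dried-sample SEM mean into the expected
wet-technique mean.

Force tomography on the QI side:

```r
m <- generate_cell_model(field_size = c(2500, 2500), n_plates = 1,
                         pores_per_plate = 10, diameter_mean = 150,
                         diameter_sd = 25, seed = 31)
force_tomography(render_qi(m, qi_preset("FA", pixel_size = 20)),
                 c(70, 140, 280))
#>   force_pN n_pores mean_d_eq_nm pct_change
#> 1       70      10     121.5678    0.00000
#> 2      140      10     167.4963   37.78018
#> 3      280      10     174.1399   43.24517
```

The formaldehyde ("FA") preset shows the strong load-force dependence of
softly fixed membranes (>25% tip-induced dilation at 280 pN); the
glutaraldehyde ("GA") preset stays below 10%.

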