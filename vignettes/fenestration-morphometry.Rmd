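---
title: "Correlative fenestration morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlative fenestration morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fencorr)
```

# The measurement problem

Liver sinusoidal endothelial cells (LSEC) are perforated by fenestrations:
open transcellular pores of roughly 50–350 nm diameter, clustered in sieve
plates of a few to a few hundred. Their size distribution is measured with
several microscopies, and the modalities disagree systematically:

* **Dehydration.** SEM requires fixed-dried samples. Cells stay spread on
  the coverslip (integrin attachment), so the cell outline is unchanged,
  but pores dilate by 30–40% in diameter. The effect is multiplicative
  and nearly uniform across pore sizes, with extra elongation at the
  edges of sieve plates.
* **PSF blur.** Fenestrations are *negative* structures — an absence of
  signal inside a labeled membrane. A Gaussian PSF of width σ shifts a
  thresholded pore edge and can hide the smallest pores entirely.
* **Tip–sample interaction.** AFM Quantitative Imaging (QI) records a full
  force–distance curve per pixel; reconstructing the topography at higher
  load forces dilates pores when the membrane rim is compliant, which
  depends strongly on the fixation chemistry (formaldehyde vs
  glutaraldehyde).

`fencorr` models all three effects with a known ground truth, measures
them with the same segmentation and matching machinery one would apply to
real images, and reports the paired statistics used to compare modalities
pore-by-pore.

# The synthetic ground truth

`generate_cell_model()` draws elliptical pores. Ellipses make roundness
(`d_min/d_max`) exact in the ground truth, matching the measurement
convention "ratio of min to max diameter assuming elliptical shape". The
equivalent-area diameter `d_eq = sqrt(axis_major * axis_minor)` is the
primary "fenestration diameter"; it satisfies `area = pi d_eq^2 / 4`
exactly, which is the relation that makes paired area-vs-diameter panels
linear. Both conventions (ellipse axes and `d_eq`) are emitted in every
pore table.

Default study conditions:

* diameter mean 158 nm, sd 40 nm (typical wet-fixed peak values),
  truncated to positive values;
* roundness mean 0.83, sd 0.09, truncated to (0.2, 1];
* sieve plates sized so that the pore *exclusion* area (pore plus
  separation band) fills ~15% of the plate disc — rejection sampling then
  terminates reliably; plates are laid on a seeded, jittered grid, which
  gives a deterministic capacity check instead of a flaky rejection loop;
* a minimum boundary separation between pores (default 30 nm; the paired
  wet/dry studies below use 100 nm so that pores remain individually
  resolvable after the largest dilation studied, λ = 1.5 — a property the
  one-to-one analyses of real data share by construction, since merged
  pores cannot be paired);
* membrane height 150 nm (sieve-plate regions are thinner than 200 nm);
* gaps as ellipses with major axis ≥ 1 µm, outside plates;
* a configurable fraction of *closed* pores — invaginations that do not
  pierce the membrane. They are invisible to SEM and optics and rendered
  as shallow depressions (40% of membrane height) in AFM topography. The
  depth is a modeling stand-in (no measured profile exists); 40% keeps
  them below the default 50% depth threshold, so detecting them requires
  deliberately changing `afm_depth_fraction`, which mirrors how they are
  genuinely hard to see outside AFM.

`apply_dehydration()` keeps centres and the field fixed and multiplies
open-pore axes by `lambda_dilation` (default 1.34; 1.33 and 1.38
correspond to the other two fixed-dried comparisons). Pores whose centre
lies in the outer `edge_fraction` (default 0.2) annulus of their plate are
additionally stretched by `edge_elongation` (default 1.3) along the plate
radial direction; this divides their roundness by the same factor, which
reproduces the observed wet-to-dry roundness drop while uniform dilation
leaves roundness untouched. The annulus model is one plausible reading of
the edge-elongation observation; no quantitative model of it exists.
Closed pores open on drying with probability `p_open_on_drying` (default
0.5 — the observation is that some opened and some stayed closed, with no
count given). Newly opened pores dilate like other open pores. Gaps are
left unchanged.

# Renderers

**SEM** (`render_sem`): membrane at gray level 200, open pores and gaps at
20, 1-px Gaussian antialias, additive Gaussian detector noise. Closed
pores render as membrane (indistinguishable). Recommended pixel size
≤ 10 nm.

**Optics** (`render_optical`): the membrane indicator is rasterized on an
oversampled grid, convolved with a normalized Gaussian PSF
(σ = FWHM/2.355), binned to the acquisition pixel size (30–39 nm),
scaled by the photon budget, and given Poisson noise over a constant
background. Poisson for photon counting and Gaussian for SEM detectors
are conventional detector models. The normalized PSF conserves expected
photons to numerical precision. Blur boundaries are edge-replicated, not
periodic — a rendered field is a crop of a larger membrane.

**AFM QI** (`render_qi`): the ground-truth height map is first
tip-convolved by grey-scale morphological dilation with a spherical tip
profile (the standard AFM dilation model; only tip radii are known).
Each pixel then receives an approach curve on a shared descending ramp
(default 600 nm, 128 samples): zero force until contact, then spherical
Hertz contact `F = (4/3)·E/(1−ν²)·√r·δ^{3/2}` against the local modulus —
substrate inside open pores, membrane elsewhere — with ν = 0.5 (standard
soft-matter assumption) and the cantilever deflection `F/k` included in
the piezo bookkeeping. Moduli ≥ 100 MPa indent by less than a nanometre
at these forces and are treated as a hard wall, which keeps rigid-sample
reconstruction exact under linear interpolation. Within a rim band around
each open pore an extra linear compliance `c(x) = rim_compliance ·
exp(−dist/rim_decay)` (decay 20 nm) lowers the surface under load, so
reconstructed pore diameters grow with load force. Two presets encode the
fixation contrast: `qi_preset("GA")` (stiff membrane, 200 kPa, rim
compliance 150 nm/nN) keeps the tomographic dilation below 10% between 70
and 280 pN; `qi_preset("FA")` (100 kPa, 1100 nm/nN) exceeds 25%. The
presets are calibrated inputs that encode the observed qualitative
behaviour, not validated predictions.

# Segmentation

Images are normalized by percentile clipping (default 0.5/99.5) to [0, 1]
— the per-image "contrast adjustment" step. Thresholding is
modality-aware:

* **Optics**: membrane level = mode of the upper intensity class (Otsu
  split, density mode, tie-break toward higher intensity); background =
  mode of the *deep* tail (pixels below half the split) — restricting the
  pool prevents the estimate drifting onto partially-filled pore dips.
  The cut level is `membrane − f·(membrane − background)` with
  `threshold_fraction` f defaulting to 0.75, i.e. the midpoint between
  the maximum-intensity level and the half-maximum of a blurred edge.
  For a straight edge this displaces the mask edge into the pore by
  exactly `σ·qnorm(f)` = 0.674σ per side (f = 0.5 is unbiased) — the
  closed form behind the smaller diameters optical techniques report.
  For curved pore edges at f = 0.5 a residual curvature bias of order
  σ²/d remains; the bias tests use straight edges where the CDF oracle
  is exact.
* **SEM**: Otsu split, unless `fixed_threshold` is given; a unimodal
  histogram (density at the split comparable to the class peaks) is an
  error advising a fixed threshold.
* **AFM topography**: pore = normalized height below `afm_depth_fraction`
  (default 0.5) of the membrane-to-floor drop; working on the normalized
  image makes the rule invariant to the uniform membrane indentation that
  grows with load force.

Components are labeled at 8-connectivity by default; diagonally adjacent
labels from the 4-connectivity pass are merged by union-find. Merged
pores are *not* split — they are measured as one component and flagged
downstream when they gate onto two partners, mirroring how adjacent pores
merge in lower-resolution modalities. Components touching the image
border are flagged and excluded from statistics (truncated diameters
would bias the distributions; the border policy is otherwise
unconstrained). Ellipse axes come from second-order central moments with
the 1/12-pixel variance correction; classes are subresolution
(< 50 nm), fenestration, and gap (≥ 350 nm). All distribution statistics
use the fenestration class only.

# Matching and registration

`fit_transform()` estimates similarity (closed-form Procrustes), affine
(linear least squares) or projective (normalized DLT) transforms from
landmark pairs; similarity is the default since two images of a flat
coverslip chiefly differ by scale, rotation and translation, and
projective mirrors the "perspective" correction workflow. Residual RMS
replaces visual quality control. `match_pores()` maps centroids, builds
the gated candidate graph (default gate 150 nm ≈ mean pore radius plus
registration slack; the original matching was visual, so no recorded
tolerance exists), decomposes it into connected components and solves
each with an optimal assignment (`clue::solve_LSAP`) on a square-padded
cost matrix — maximal cardinality first, minimal total distance second.
The assignment problem separates exactly over disconnected components, so
the decomposition preserves global optimality while keeping thousands of
pores fast.

# Statistics

"Mean fenestration size" is the fitted Gaussian peak μ of the diameter
histogram (bin 10 nm; roundness bin 0.05 — the fit procedure is standard,
bin widths are ours), not the histogram mode or the sample mean. If the
nonlinear fit fails, lands outside the data, disagrees with the sample
mean by more than σ, or (for well-populated histograms, max count ≥ 30)
explains less than 60% of the count variance — the bimodal case — the
sample mean/sd are reported with a `fallback` flag. Paired regressions
use ordinary least squares with a free intercept (reported diameter
slopes below the mean ratio imply a nonzero intercept was present; forcing
zero would change the estimand). Reported ratios and percentages use
half-up rounding at 2 decimals / integers, with full precision always
retained. `percent_change` and `correction_coefficient` are exact
inverses: ratio = 1/(1 + pct/100).

# Numerical choices

* Blur: separable shifted-sum convolution for kernels up to ~10 px;
  FFT on a replicate-padded matrix beyond that.
* QI curve synthesis inverts `s = δ + (c + 1/k)·A·δ^{3/2}` by 50-step
  bisection (`~1e-15` relative); pixels sharing (height, modulus,
  compliance) share one curve, which collapses most of the grid.
* Topography reconstruction interpolates linearly in (z, F); when the
  bracketing segment spans the contact kink (lower sample still at zero
  force) the first fully post-contact segment is used instead, which is
  exact for a hard wall. With ≥ 64 samples over ≤ 800 nm the
  interpolation error stays below 1 nm.
* Contact detection: baseline = median of the first 25% of samples;
  contact = largest piezo height with force above 3× the noise floor for
  ≥ 3 consecutive samples. Chosen over derivative methods for noise
  robustness; threshold crossings always trail the true contact, so the
  Hertz fit refines the contact height upward by RSS minimization with a
  closed-form prefactor per candidate.
* The Hertz fit caps at 200 pN by default — low-force analysis probes the
  cortical layer (50–200 nm indentation with a 7.9 µm colloidal probe)
  rather than deeper structures. The cap is interpreted as
  "fit restricted to F ≤ 200 pN" (the alternative reading, evaluation at
  200 pN, coincides for a noiseless Hertz curve).
* The default QI reconstruction force in the pipeline convention is 90%
  of the maximal load force, the setting that gives clear fenestration
  images.

# What the tests show — and what they cannot

The test suite validates every stage against independent oracles:
closed-form ellipse geometry and pixel-count rasterization; the
Gaussian-CDF edge oracle; exhaustive-permutation assignment; per-pixel
brute-force curve scans; generator round trips at known λ and E. The
dilation-recovery suite runs the full render → segment → match → fit
pipeline at λ ∈ {1.2, 1.34, 1.5} with 2000 pores and recovers the peak
ratio and regression slopes to well within a few percent. Problem sizes
(fields of 20–42 µm at 10 nm/px, 500–2000 pores, 16×16 to 170×170 QI
grids) were chosen as the smallest at which the distributional statistics
are stable.

Both arms of the dilation-recovery study are rendered with the crisp
SEM-style renderer. This isolates the dehydration estimand from the
PSF-threshold bias, which is characterized separately by the edge-oracle
suite; running the wet arm through the optical renderer at the 0.75
threshold fraction superimposes the known 0.674σ deficit on the wet
diameters, which is exactly the confound the correlative design exists to
expose. The shipped pipeline default therefore uses the unbiased
half-maximum cut (`threshold_fraction: 0.5` in
`inst/extdata/default_config.yaml`); setting 0.75 reproduces the
max-to-FWHM cut-off convention and its bias.

Passing on synthetic data shows the *machinery* is correct, not that the
simulator reproduces real LSEC images. The generator does not model:
labeling density or photobleaching, SIM reconstruction artifacts,
out-of-focus perinuclear membrane signal (the main cause of missed sieve
plates in optics), 3-D membrane topology such as fenestration labyrinths,
drift or vibration, or pore-size changes in live cells. Measured means on
real data depend on sieve-plate selection; per-experiment values are
comparative, not population estimates.

# Known limitations

* The rim-compliance model is phenomenological; it encodes the direction
  and approximate magnitude of tip-induced dilation, not membrane
  mechanics.
* Closed-pore geometry (depth, profile) is a stand-in.
* Background estimation assumes some genuinely dark area (a gap or deep
  pores) exists in the field; on images of uniformly small, shallow dips
  the optical threshold will be biased low and pores will be missed —
  matching the practical experience that such images need manual cut-off
  selection.
* `match_pores` resolves merged components by nearest-distance assignment
  and a `merged_candidate` flag; it does not split them.
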