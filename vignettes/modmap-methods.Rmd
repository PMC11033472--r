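---
title: "Quantifying patch/interpatch organization of horizontal connections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying patch/interpatch organization of horizontal connections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmap)
```

## The analysis problem

Layer 1 of mouse primary visual cortex (V1) is tiled by alternating
modules on the ~100 um scale: M2 muscarinic acetylcholine receptor-rich
*patches* and M2-negative *interpatches*. Long-range horizontal axons,
the cell bodies of the neurons that send them, and those neurons' apical
dendrite tufts can each be biased toward one module class, and
quantifying that bias from tangential (flatmount) sections requires a
chain of image operations: delineating the module mosaic from a
fluorescence channel, aligning serial 40 um sections to the L1 reference
frame where the mosaic is defined, and conditioning density measurements
(optical density of axons, counts of plotted cell bodies and dendrites)
on module class and on distance from the tracer injection.

`modmap` implements this chain as composable, seeded, unit-tested
functions, and pairs it with a synthetic-scene generator that plants
known ground truth, so every stage can be validated quantitatively
without tissue data.

## Module delineation

`delineate_modules()` composes three steps, in this order:

1. **Local-mean normalization** (`normalize_local()`): each pixel is
   divided by the mean intensity of the surrounding disc of radius
   `norm_radius_um` (default 100 um). This is a high-pass operation: it
   removes illumination and labeling-density gradients that are smooth at
   scales beyond ~2x the disc radius while passing the ~120 um module
   pattern. It also makes the result invariant to global intensity
   scaling, so arbitrary fluorescence units never matter.
2. **Circular-average blur** (`blur_circular()`, default radius 30 um),
   suppressing pixel noise below the module scale.
3. **Equal-count sextile partition** (`quantile_partition()`): masked
   pixels are ranked and cut into 6 classes of equal count; the top 2
   are the patch mask, the bottom 2 the interpatch mask, and the middle
   2 are deliberately left out of the two-class comparison.

Numerical choices worth knowing:

* Both disc filters are *masked normalized convolutions*: the mean is
  taken over disc ∩ mask. Zero- or reflect-padding at tissue edges would
  bias edge pixels toward low (or duplicated) intensities and hence
  systematically misassign edge quantiles; dividing two zero-padded FFT
  convolutions (signal x mask and mask alone) gives the exact in-mask
  disc mean everywhere. Both filters are verified against explicit
  per-pixel disc enumeration to 1e-9.
* A pixel belongs to the disc iff its centre lies within the radius,
  inclusive. A radius below one pixel is a parameter error.
* Tied intensity values always fall to the *lower* quantile, which makes
  the partition deterministic across platforms; each class count then
  deviates from N/6 by at most the number of boundary ties (plus at most
  one pixel when N is not divisible by 6, from the ceil-rank boundary).
* An image whose masked values are constant (relative range below 1e-9)
  is a degenerate-partition error, not an arbitrary labeling.
* A pixel's quantile is computed V1-wide (the supplied mask), not per
  ROI: module identity is a property of the map, while ROIs only select
  where densities are read out.

The same normalize + blur pair is applied to the axon channel before
per-quantile optical densities are read out; local-mean division is the
natural reading of high-pass filtering for this purpose and uses the one
set of radii the delineation step defines.

## Serial-section registration

Sections are aligned on blood-vessel landmarks with a planar projective
(homography) transform per section, fitted by the normalized direct
linear transform: both point sets are conditioned to zero mean and unit
RMS, the 2n x 9 system is solved by SVD, and the conditioning is undone.
The fit is exact for 4 non-degenerate pairs and least-squares beyond;
degenerate configurations (collinear landmarks) are detected from the
singular spectrum. Transforms act on physical um coordinates — sections
may differ in pixel grid — with the convention that the origin is the
upper-left pixel centre and x runs along columns.

Intensity images are resampled by inverse mapping with bilinear
interpolation; module label maps are transported nearest-neighbor
(`propagate_modules()`) so labels never blend. Layer identity is a
lookup from section index (`assign_layer()`), defaulting to the
PV/Ctip2-calibrated table (sections 1-2 = L1, 3-7 = L2-4, 8-12 = L5,
13-16 = L6, beyond = unknown); the table is configuration, not
something the package re-derives. The number of landmarks per section
and any residual threshold are likewise configuration with no enforced
default, since acceptable residuals depend on tissue distortion; fitted
residual RMS (um) is always reported.

## Module-conditioned quantification

* `roi_quantile_density()` reads mean optical density per intensity
  sextile inside 550 x 400 um ROIs (3 per section by default). A
  quantile absent from an ROI is reported missing, never as zero
  density. Per-ROI sums satisfy the conservation identity
  sum(mean x count) = total ROI signal to 1e-12.
* `radial_density_profile()` bins signal (or points) into 50 um annuli
  around the injection centre, starting at the core-exclusion radius —
  250 um for axon profiles, 300 um (a 600 um-wide core) for point
  profiles, since the saturated core is unquantifiable. Density is
  sum/area per module class per annulus; *both* class curves are divided
  by one shared constant, their joint maximum, so the peak equals 1 and
  the patch/interpatch contrast is preserved. The exclusion disc is a
  circle; for non-circular cores this is an approximation. SEM is
  computed across replicates when supplied. A 3-bin moving average is
  attached for display only; all statistics use raw bins.
* `estimate_preference_ratio()` summarizes a profile as the
  area-weighted mean of per-annulus interpatch/patch density ratios —
  a distance-controlled estimate of the modular preference.
* `ks_compare()` applies the two-sample Kolmogorov-Smirnov test to
  per-ROI patch means vs interpatch means (ROIs are the sampling units;
  a 4-subject x 3-ROI study gives N = 12 per sample). p-values are
  exact for both n <= 25, asymptotic beyond.
* `anisotropy_aspect_ratio()` measures elongation as
  sqrt(lambda_major / lambda_minor) of the intensity-weighted second
  central moment matrix over super-threshold pixels (default: top
  quartile). Moments rather than a fitted ellipse contour: they are
  deterministic, rotation invariant up to discretization, and invariant
  to intensity scaling. The major-axis angle is reported in degrees.
* `detect_injection_center()` takes the intensity-weighted centroid of
  pixels at or above a saturation quantile; the core radius is supplied
  by the analysis, never estimated. Isolating a single saturated pixel
  among N requires a quantile above 1 - 1/N.

Points (cell bodies, apical dendrites) enter as pre-classified CSV —
identifying an apical dendrite morphologically is a manual call — and are
assigned module classes by nearest-pixel lookup after registration into
the L1 frame.

## The synthetic scene generator

`simulate_scene()` plants every quantity the pipeline estimates:

* **Module field**: Gaussian white noise band-pass filtered with a
  difference-of-Gaussians transfer (sigma2 = 2 sigma1, sigma1 set so
  the peak response sits at `module_spacing_um`). This reproduces the
  quasi-periodic, non-crystalline look of the patch mosaic without
  lattice placement heuristics. Ground truth is the sextile partition
  of the raw field. The default 120 um spacing on a 2560 x 2560 um
  field at 5 um/px yields 4-8 modules per 260 x 360 um point-image
  window; the true biological period is not established, so spacing is
  a free parameter.
* **Axon field**: `exp(-d/L)` in elliptical distance d (major axis along
  elevation, axis ratio `anisotropy_a`, default 1.4, matching the
  observed regime; decay length 500 um, putting resolvable structure
  from the ~400-500 um halo outward), multiplied by
  `1 + (rho - 1) x [interpatch]` and by log-normal unit-mean speckle
  (sigma 0.2) — multiplicative because fluorescence noise is
  non-negative and signal-proportional. The planted `rho` is the
  interpatch/patch density ratio at matched distance; `rho = 1` is the
  null. A 200 um-radius core is set to a saturated constant.
* **Points**: inhomogeneous Poisson samples drawn by thinning against
  the field maximum (exact, no gridding bias), expected counts 1000
  each for cells and dendrites, suppressed inside the core where real
  counts are unresolvable.
* **Serial stacks**: per-section homographies as small identity
  perturbations (translation at the distortion scale, linear terms
  scaled by field extent, projective terms a further factor 10 down),
  with exact landmark correspondences and truth transforms returned.

Sub-generators draw from split, deterministically derived seed streams,
so changing the landmark count cannot perturb the axon field. Every
generator is a pure function of (parameters, seed).

What the generator does *not* emulate: real vessel appearance and
landmark localization error, section-to-section staining variability,
laminar 3D morphology, per-axon trajectories, or non-elliptical
injection cores. Passing the planted-recovery tests therefore
demonstrates correctness of the measurement chain, not robustness to
every tissue artifact.

## Statistical calibration and study sizes

The two-sample KS statistic at equal sample sizes n is discrete (D
takes values k/n), so the achievable test size at alpha = 0.05 depends
strongly on n: at the tissue study's N = 12 sampling units the exact
size is 0.0314 — conservative — and the unit tests check the observed
null rejection rate against that exact value as the oracle. For the
package's end-to-end calibration experiment we instead simulate studies
with 22 ROI sampling units, where the exact size is 0.0494, the
attainable level closest to nominal among small equal-n designs
(computed from the exact null distribution across n = 10..120 before
any simulation was run). Per-ROI patch and interpatch means use
disjoint pixel sets of a high-pass-filtered signal, which removes the
shared distance-decay component that would otherwise correlate the two
samples and make the test arbitrarily conservative.

Problem sizes used by the validation suite, chosen as reduced-scale
study designs: calibration and power runs use 1600 x 1600 um scenes at
10 um/px with 180 x 140 um ROIs (2000 null replicates, 100 power
replicates at rho = 4); preference-ratio recovery uses the full default
scene (10 seeds per planted rho in {1, 2, 4}); anisotropy recovery uses
the default scene scale, where the circular 250 um core-exclusion hole
leaves the moment ratio essentially unbiased (at much smaller scales
the circular hole in an elliptical field inflates the ratio — a known
limitation of moment-based anisotropy with core exclusion).

## A worked example

```{r example, eval = FALSE}
scene <- simulate_scene(seed = 1, interpatch_preference_rho = 2)
res <- analyze_scene(scene, seed = 1)
res$preference_ratio      # ~2: the planted interpatch preference
res$ks                    # patch vs interpatch per-ROI means
res$anisotropy            # ~1.4 along the elevation axis
plot(res$axon_profile)
```

`run_pipeline()` is the file-based equivalent: a YAML config pointing
at TIFFs and CSVs in physical units, producing CSV/JSON tables plus a
provenance manifest; identical config and seeds reproduce outputs
byte-identically.

## Known limitations

* The delineation's Dice against ground truth is ~0.83 even without
  noise: the normalization and blur radii reshape the field slightly
  relative to the raw-field sextiles that define truth. This attenuates
  estimated preference ratios measured through a *delineated* (rather
  than ground-truth) map by roughly 10%.
* Joint-maximum normalization of profiles is one convention among
  several; the normalization constant is attached to the profile so
  other conventions can be recovered.
* The anisotropy estimate inherits the bias described above when the
  exclusion hole is large relative to the labeled field.
* Exact KS p-values are only used up to n = 25 per sample; beyond that
  the asymptotic distribution is adequate at these sample sizes.
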