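# modmap

Quantifies the modular — patch/interpatch — organization of horizontal
connections in tangential sections of mouse primary visual cortex (V1).

Layer 1 of mouse V1 is tiled by ~100 um-scale modules defined by M2
muscarinic acetylcholine receptor immunostaining: M2+ *patches* and M2−
*interpatches*. Long-range horizontal axons, the somata of the neurons
that send them, and their apical dendrite tufts can each prefer one
module class. `modmap` is for anatomists who trace these circuits in
flatmounted cortex and need the measurement chain behind such claims:

1. **Segmentation** — delineate patches/interpatches from a fluorescence
   image: divide each pixel by its surrounding 100 um-radius disc mean
   (high-pass, scale invariant), blur with a 30 um-radius circular
   averaging filter, partition the masked intensities into 6 equal-count
   quantiles; the top 2 are patches, the bottom 2 interpatches.
2. **Registration** — align serial 40 um sections to the L1 reference
   frame via projective transforms `H` (3x3 homographies acting on um
   coordinates) fitted to blood-vessel landmarks by the normalized DLT;
   propagate the L1 module map to deeper sections (nearest-neighbor, no
   label blending); map section index to layer (1–2 → L1, 3–7 → L2-4,
   8–12 → L5, 13–16 → L6).
3. **Quantification** — per-quantile optical density in 550 x 400 um
   ROIs; radial density profiles `d_c(r) = S_c(r) / A_c(r)` per module
   class `c` in 50 um annuli around the injection centre with the
   saturated core excluded (250 um radius for axons, 300 um for points),
   jointly normalized to peak 1; interpatch/patch preference ratio;
   point densities per mm^2; two-sample Kolmogorov–Smirnov comparison of
   per-ROI patch vs interpatch means; anisotropy as
   `sqrt(lambda_major/lambda_minor)` of intensity-weighted second
   central moments.
4. **Synthetic scenes** — a seeded generator that plants all of the
   above (band-pass module mosaic, anisotropic distance-decaying axon
   field with interpatch preference `rho`, Poisson point sets, distorted
   serial stacks with exact landmark correspondences), so the whole
   chain is validated against known ground truth.

## Worked example

```r
library(modmap)

scene <- simulate_scene(seed = 1, interpatch_preference_rho = 2)
res   <- analyze_scene(scene, n_rois = 12, seed = 1)

res$preference_ratio
#> [1] 1.838198
res$ks
#> KS comparison: D = 1.0000, p = 7.4e-07 (n = 12 vs 12) *reject at alpha = 0.05*
res$anisotropy
#> anisotropy: aspect ratio 1.420, major axis 90.4 deg (n = 63571)
print(res$quantile_density$summary, digits = 3)
#>   quantile  mean     sem n_roi
#> 1        1 1.288 0.00439    12
#> 2        2 1.130 0.00314    12
#> 3        3 1.009 0.00322    12
#> 4        4 0.919 0.00247    12
#> 5        5 0.856 0.00231    12
#> 6        6 0.785 0.00249    12
```

The scene plants a 2x interpatch preference in the axon field. The
recovered ratio of 1.84 is read from the radial profile through the
*delineated* module map (imperfect delineation attenuates it slightly;
through the ground-truth map it recovers ~2.0). Mean filtered axon
density falls monotonically from intensity quantile 1 (interpatch) to 6
(patch), the KS test on 12 per-ROI means rejects equality decisively,
and the planted 1.4 anisotropy along the elevation axis (90 deg) is
recovered from the second moments. `plot(res$axon_profile)` draws the
normalized patch/interpatch density curves against distance from the
injection centre.

File-based runs use `run_pipeline("config.yaml")` (TIFF images, CSV
landmarks/points, um units throughout), or the shell wrapper in
`inst/scripts/modmap` with subcommands `simulate`, `segment`, `align`,
`quantify`, `report`. Identical configuration and seeds reproduce
outputs byte-identically.

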