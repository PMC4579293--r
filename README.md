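# tractdissect

Virtual dissection of white-matter pathways by probabilistic tractography,
exercised end to end on synthetic diffusion phantoms with known ground
truth.

The package addresses a concrete neuroanatomy problem: isolating, from
diffusion-weighted MRI, a putative subcortical pathway that runs from the
superior colliculus (SC) through the pulvinar to the lateral amygdala. The
pathway's terminal segment arcs over the temporal horn of the lateral
ventricle alongside the stria terminalis, so a naive dissection is
contaminated by crossing fibers; the protocol implemented here dissects the
stria first and re-dissects the pathway with the unthresholded stria
streamline as an exclusion mask, then quantifies the spatial separation of
the two tracts with per-slice centre-of-gravity (CoG) statistics and asks
whether focal lesions would interrupt the pathway.

It is intended for methodologists who want a tested, reproducible,
self-contained implementation of this dissection logic — mask-role
semantics, visitation-map algebra, composite rules, CoG variability tables,
lesion reports — that can be validated against ground truth rather than
eyeballed on subject data.

## The model and the pipeline

Per voxel, the diffusion signal follows the single-stick ball-and-stick
model

    S(g, b) = S0 * [ (1 - f) exp(-b d) + f exp(-b d (g . v)^2) ]

with stick orientation `v`, anisotropic fraction `f` and diffusivity `d`.
`fit_ball_stick()` estimates it by nonlinear least squares followed by
Metropolis sampling of `(v, f)`. `track()` propagates streamlines through
the sampled orientation field (curvature threshold 0.2, 5000 samples per
seed voxel by default) under seed / waypoint / termination / exclusion
mask roles, counting each retained streamline once per visited voxel.
`dissect_pathway()` runs the full protocol; `threshold_map()` keeps voxels
with at least 10% of the maximum count; `composite()` implements
at-least-N-of-M participant rules; `cog_profile()`,
`variability_table()` and `compare_offsets()` produce the tract-separation
statistics (two-factor ANOVA, streamline effect tested against the
streamline-by-participant interaction); `intersect_lesion()` reports
lesion interruption. `sc_amygdala_phantom()` and `simulate_phantom()`
generate the study phantoms, including a two-bundle crossing confound and
Rician noise at controllable SNR.

## Worked example

```r
library(tractdissect)

scheme <- make_scheme(60, 1000, n_b0 = 11, rng_seed = 2)
spec   <- sc_amygdala_phantom(two_bundle = TRUE)   # noiseless by default
sim    <- simulate_phantom(spec, scheme)

fit <- fit_ball_stick(sim$dwv, K = 25, rng_seed = 3)
dr  <- dissect_pathway(fit, sim$truth$rois,
                       config = tracker_config(samples_per_seed_voxel = 500,
                                               rng_seed = 11),
                       bidirectional = TRUE)
dr
#> Virtual dissection result
#>   stria run:        14393 retained
#>   SC-amygdala:      33444 retained (no exclusion)
#>   SC-amygdala:      6224 retained (stria excluded)
#>   thresholded pathway: 223 voxels
#>   bidirectional overlap continuous: TRUE

dice_coefficient(dr$sc_amygdala_raw, sim$truth$bundles$sc_amygdala$mask)
#> [1] 0.8055988

cog_profile(dr$sc_amygdala_raw, slices = 31:38, label = "pathway")
#> Per-slice centre-of-gravity profile (pathway)
#>  slice     x_mm     z_mm
#>     31 29.28571 23.50000
#>     32 29.35714 23.21429
#>     ...
```

Reading the output: the stria dissection retained 14,393 streamlines; the
raw SC–amygdala dissection 33,444, of which 6,224 survive re-tracking with
the stria exclusion; the 10%-thresholded pathway recovers the ground-truth
bundle with Dice 0.81 and overlaps continuously with the reverse
(amygdala-seeded) dissection. Over the segment above the temporal horn
(coronal slices 31–38) the pathway's CoG runs about 1.4 mm medial to the
stria's — the kind of tract-separation evidence the CoG analysis is for.
The full example takes about two minutes on one core, most of it in the
voxelwise model fit.

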