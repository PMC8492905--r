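# octafd

Quantifying the complexity of the macular microvasculature in OCTA images
with the box-counting fractal dimension.

## The problem

Optical coherence tomography angiography (OCTA) images the retinal capillary
network non-invasively, layer by layer: the superficial (SCP), deep (DCP) and
whole (WCP) capillary plexus of the macula. In neuroinflammatory diseases
such as neuromyelitis optica spectrum disorder (NMOSD), capillary dropout
simplifies the geometry of this network. A scale-free summary of that
geometry is the box-counting fractal dimension of the skeletonized vessel
network,

    D_box = slope of log N(eps) vs log(1/eps),

where `N(eps)` is the number of `eps x eps` grid boxes containing at least
one skeleton pixel. A fully space-filling network approaches 2, a single
smooth vessel approaches 1; healthy parafoveal capillary beds measure in
between, and drop with capillary loss.

`octafd` implements the whole measurement chain for 3 x 3 mm en face
angiograms —

1. **segment**: multiscale Frangi vesselness + Otsu-gated hysteresis
   thresholding to a binary vessel map (a classical stand-in for a learned
   segmenter, behind the same interface);
2. **FAZ**: detection of the foveal avascular zone by morphological closing
   and center-component extraction;
3. **ROI**: the parafoveal annulus of 0.6–2.5 mm diameter around the foveal
   center, with the FAZ excluded;
4. **skeletonize**: Guo–Hall thinning to 1-px centerlines (topology
   preserved);
5. **D_box**: single-grid box counting inside the mask, OLS fit in log–log
   space;

— plus the cohort statistics used in inter-eye-clustered ophthalmic studies
(GEE with exchangeable working correlation and robust errors, correlation
inference from summary statistics, LogMAR conversion, signal-quality
filtering at SQ ≥ 6), and a synthetic-data module: known fractals with
closed-form dimension, vascular-tree angiograms with ground truth, and
simulated two-eyed cohorts with configurable group effects, inter-eye
correlation and a disability (EDSS) link.

This package is for researchers who want a tested, reproducible, scriptable
D_box pipeline for OCTA-style images — or a simulation bench to validate one.

## Worked example

```r
library(octafd)

# a synthetic angiogram with known ground truth
sa  <- generate_vasculature(synth_vasc_params(noise_sd = 0.02), seed = 3)
res <- compute_dbox(sa$image)
res
#> <dbox_result> D_box = 1.5107 (R^2 = 0.9958, 7 scales)

# the estimator recovers closed-form dimensions
koch <- generate_known_fractal("koch_curve", 1024, 6)
fit_dbox(box_count(koch, box_sizes_px = c(2, 4, 8, 16, 32, 64)))$dbox
#> [1] 1.216614    # theory: log(4)/log(3) = 1.2619

# correlation inference from summary statistics (r, n)
p_from_r(-0.475, 34)
#> <correlation_result> pearson r = -0.475, n = 34, p = 0.00453
```

The `dbox_result` holds the box-count curve, the log–log fit (slope = D_box,
R² of the fit) and all intermediates (vessel map, skeleton, FAZ, annulus)
for audit. A cohort-level run:

```r
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "octafd"))
report <- run_pipeline(cfg)
report$comparisons[1:3, c("layer", "group1", "group2", "difference", "p_value")]
#>   layer group1    group2  difference      p_value
#> 1   SCP     HC NMOSD_NON -0.03402671 4.212009e-04
#> 2   SCP     HC  NMOSD_ON -0.06252360 1.180975e-13
#> 3   SCP NMOSD_NON NMOSD_ON -0.02849688 7.962450e-03
```

Each row is an adjusted mean D_box difference (group2 minus group1) from a
linear GEE with subjects as clusters (two eyes each), adjusted for age, sex
and signal quality, with a robust Wald p-value. Negative differences mean a
simpler capillary network in the second group.

## Command line

```sh
octafd simulate fractal --kind koch_curve --size 1024 --iters 6 --out koch.png
octafd simulate cohort --seed 17 --out-dir sim/
octafd segment --in eye.png --extent-mm 3.0 --out vessels.png
octafd fd --in vessels.png --box-sizes 2,4,8,16,32,64 --out result.json
octafd run --config inst/extdata/demo_config.yaml --out report/
```

(`octafd` is the installed `exec/octafd` wrapper; equivalently call
`octafd::cli_entry(c("fd", "--help"))` from R.)

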