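# octfractal

Quantifying structural disorder of intraretinal layers in optical coherence
tomography (OCT) B-scans. In early diabetic retinopathy, neurodegeneration
changes the texture of retinal layers before gross thickness changes become
reliable; this package measures that disorder as a **fractal dimension** of
each layer's depth reflectivity profile and asks, layer by layer, how well
it separates diseased from healthy eyes compared with conventional
thickness and reflectivity morphometry.

It is written for image-analysis researchers working with segmented retinal
OCT: the inputs are plain B-scan rasters (TIFF/PNG or numeric text) plus a
CSV of layer-boundary positions produced by any segmentation tool, and the
outputs are per-eye feature tables and a per-layer statistical comparison.

## The measurement

For each A-scan and each of the 7 layers (RNFL, GCL+IPL, INL, OPL, ONL+IS,
OS, RPE) the depth reflectivity profile is Fourier transformed; its power
spectrum follows a power law

P(&omega;) &prop; &omega;<sup>&minus;&beta;</sup>,

the exponent &beta; is minus the slope of the least-squares line through
the log–log periodogram, and the fractal dimension is

FD = (5 &minus; &beta;) / 2,

so FD &isin; (1, 2), larger = rougher/more disordered. Per-layer FD is the
mean over A-scans, per-eye FD the mean over scans. Blood-vessel shadows
(dark vertical columns) are located on a *shadowgram* — the lateral
profile of outer-retina intensity — by a robust threshold and excluded
from all reflectivity-based measurements. Layer thickness (mean boundary
distance × axial pitch) and RPE-normalized mean reflectivity complete the
feature set. Groups are compared with one-way ANOVA + Newman–Keuls at
p < 0.001 and with ROC statistics: AUROC ± Hanley–McNeil SE, 95% CI,
a mean-minus-2SD (or Youden) cutoff, sensitivity, specificity and the
positive likelihood ratio sens/(1 &minus; spec).

A synthetic retinal phantom (`phantom_spec()`, `generate_bscan()`,
`make_eye()`, `make_cohort()`) plants known boundaries, per-layer spectral
exponents, optional speckle and vessel shadows, so every stage is
validated against ground truth. See `vignettes/oct-fractal-methods.Rmd`
for the full model, parameter defaults and their rationale.

## Worked example

Generate one phantom B-scan, estimate the GCL+IPL fractal dimension, then
run a small two-group phantom study end to end:

```r
library(octfractal)

spec <- phantom_spec(seed = 1)        # 512 A-scans x 1024 px, 7 layers
ph   <- generate_bscan(spec)
ph$image
#> <bscan phantom / eye eye>  1024 depth px x 512 A-scans, pitch 2 x 11.7 um

layer_fd(ph$image, ph$truth$boundaries, "GCL+IPL")
#> <layer_fd_summary GCL+IPL> mean FD 1.6867 (sd 0.1955) over 511/512 A-scans
#>   excluded: shadow=0, too_short=0, invalid=1
```

The planted GCL+IPL FD is 1.68: the per-scan mean over 511 usable A-scans
recovers it to 0.007, with one A-scan excluded for an out-of-range fit.
A complete study — 8 healthy vs 8 "MDR" phantom eyes whose only planted
difference is GCL+IPL FD (1.68 ± 0.01 vs 1.58 ± 0.05) — runs with one
call and prints a per-layer comparison table (FD rows shown):

```r
demo <- run_phantom_demo(out_dir = tempfile(), seed = 7)
cmp  <- demo$comparison
cmp[cmp$feature == "fd", ]
#> Layer comparison (alpha = 0.001, orientation: disease low, cutoff rule: mean_minus_2sd)
#>    layer feature healthy_mean healthy_sd diseased_mean diseased_sd         p
#>     RNFL      fd        1.722   0.007395         1.728     0.04636 7.450e-01
#>  GCL+IPL      fd        1.681   0.014349         1.594     0.04062 5.431e-05
#>      INL      fd        1.732   0.023589         1.756     0.04025 1.550e-01
#>      OPL      fd        1.514   0.016534         1.500     0.01180 7.203e-02
#>   ONL+IS      fd        1.774   0.013871         1.798     0.04423 1.595e-01
#>       OS      fd        1.587   0.079292         1.569     0.08182 6.636e-01
#>      RPE      fd           NA         NA            NA          NA        NA
#>  significant  auroc auroc_se cutoff plr
#>        FALSE 0.4844   0.1487  1.708 Inf
#>         TRUE 1.0000   0.0000  1.652 Inf
#>        FALSE 0.2500   0.1258  1.684 Inf
#>        FALSE 0.7812   0.1193  1.481 Inf
#>        FALSE 0.2812   0.1314  1.746 Inf
#>        FALSE 0.5625   0.1474  1.429 Inf
#>           NA     NA       NA     NA  NA
```

Only the GCL+IPL FD row separates the groups (AUROC 1.0 at this desk
scale, significant at p < 0.001); the mean-minus-2SD cutoff lands two
healthy SDs below the healthy mean (here 1.652), and the RPE row is
missing because a 6-pixel-thick layer cannot support a spectral fit at
2 µm axial pitch — it is excluded, not guessed. The same machinery works
on real data via `run_pipeline()` with a JSON config pointing at an image
directory, a boundary CSV and an eye/group metadata CSV; a thin CLI lives
in `inst/cli/octfd.R` (`phantom`, `shadows`, `run`, `demo` subcommands).

With the reference normative moments shipped in `reference_moments()`
(healthy GCL+IPL FD 1.68 ± 0.01), the mean-minus-2SD rule gives the
familiar FD ≤ 1.66 decision threshold.

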