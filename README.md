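# pemscope

Spatial quantification of microglia–pericyte associations on brain
microvasculature.

A subset of brain microglia lives directly against capillaries
(capillary-associated microglia, **CAM**), and a smaller subset sits
directly adjacent to capillary pericytes — the mural cells that regulate
capillary diameter and blood–brain-barrier integrity. These
pericyte-associated microglia (**PEM**) are defined spatially: a
microglia is a PEM when its nucleus/soma center lies strictly within
10 µm of a pericyte nucleus center, the pericyte residing on a vessel
below 10 µm in diameter; it is a CAM when its center lies within 10 µm of
such a vessel's centerline. `pemscope` is for researchers who have cell
coordinate exports (e.g. from manual counting in image-analysis software)
and vessel centerline traces, and who want the complete downstream
analysis:

- **CAM/PEM classification** with exact point-to-polyline distances,
  vessel-diameter eligibility, and the boxed-ROI / grid counting
  protocols used for tissue sections;
- **a Monte-Carlo chance null** for the PEM percentage — observed
  proportions only mean something relative to chance — with the analytic
  Poisson benchmark
  `P = 1 − exp(−λ_p π r²)` (2D) / `1 − exp(−λ_p 4/3 π r³)` (3D) and a
  pooled enrichment report (`observed % / expected %`);
- **vascular-tree analysis**: branch orders from the penetrating
  arteriole (order 0) to the ascending venule (order 8), per-order cell
  distributions, and vessel width at vessel-only (VO), pericyte (P), CAM
  and PEM landmarks with branchpoint exclusion;
- **longitudinal tracking** across imaging days (0/4/7/28 by default):
  mutual-nearest-neighbour matching, PEM retention curves, gain/loss
  events, and paired width change where a pericyte gained or lost a PEM;
- **ROI intensity quantification**: plane projection, rolling-ball-style
  background subtraction, mean intensity in pericyte outlines expanded by
  0.25 µm, compared between pericytes with and without a PEM;
- **a synthetic microvascular scene generator** — branching tree, cells,
  time series, intensity stacks — with ground truth, which is the test
  bed for every stage.

## Worked example

Generate a two-photon-like field, classify it, and test the observed PEM
proportion against chance:

```r
library(pemscope)

cfg    <- generator_config(seed = 2)      # 210 x 210 x 130 um field
scene  <- generate_scene(cfg)
labels <- classify_cells(scene$cells, scene$network,
                         association_criteria(use_nucleus_center = FALSE))
labels
#> <association_result> 63 microglia, 17 pericytes
#>   CAM 36.5%  PEM 6.3%  CAM-that-are-PEM 17.4%  pericytes with PEM 23.5%

null <- simulate_chance_pem(scene$cells, cfg$roi_extent,
                            chance_config(n_iterations = 500, seed = 2),
                            observed_pct = labels$summary$pct_pem)
null
#> <chance_result> observed 6.35% vs expected 1.27 +/- 1.43% (x5.00), 500 iterations
```

36.5% of the microglia are CAM and 6.3% are PEM; repositioning the
microglia uniformly at random (pericytes fixed) yields only 1.27 ± 1.43%
PEM per iteration, so the observed proportion is a five-fold enrichment
over chance in this scene. Follow the same field over a month of imaging
days and measure what happens at pericytes that gain or lose their PEM:

```r
series <- simulate_timepoints(scene, config = cfg, seed = 3)
pem_retention(series)
#>   day n_day0 n_retained retained_frac n_same_partner same_partner_frac
#> 1   4      4          4          1.00              4              1.00
#> 2   7      4          4          1.00              4              1.00
#> 3  28      4          1          0.25              1              0.25

width_change_on_gain_loss(series)$events
#>   pericyte_id type day_before day_after width_before width_after pct_change
#> 1           7 gain          0        28     4.713939    5.656727         20
#> 2          10 loss          0        28     5.072623    4.616087         -9
```

All four day-0 PEM persisted to day 7 but only one remained adjacent to
a pericyte by day 28 (the generator's cumulative retention is 44%, so a
cohort of four scatters widely). One pericyte gained a PEM over the
month and the capillary beneath it widened by 20%; one lost its PEM and
narrowed by 9%. `run_pipeline(cfg, "out/", seed = 1)` chains every
stage — classification, chance null, branch orders, widths, tracking,
intensity — and writes labeled tables, summary JSON and a run manifest.

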