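---
title: "Quantifying microglia-pericyte associations with pemscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglia-pericyte associations with pemscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemscope)
```

## The scientific problem

A subset of brain microglia resides directly against the capillary wall
(capillary-associated microglia, CAM), and a smaller subset sits directly
adjacent to capillary pericytes — the contractile mural cells that regulate
capillary diameter and blood-brain-barrier integrity. These
pericyte-associated microglia (PEM) are a *spatial* class: a microglia is a
PEM when its nucleus (or soma) center lies within 10 µm of a pericyte
nucleus center, with the pericyte residing on a capillary below 10 µm in
diameter. Because a proximity definition can be satisfied by chance, the
observed PEM proportion only means something relative to a null model; and
because the associations are dynamic, they must be followed over repeated
imaging sessions in registered coordinates.

`pemscope` implements this whole analysis chain as composable functions:

1. **associate** — CAM/PEM classification from cell-coordinate tables and a
   vessel centerline network, plus the boxed-ROI and grid counting
   protocols used for tissue sections;
2. **chance** — a Monte-Carlo null for the PEM percentage with an analytic
   Poisson oracle;
3. **vasctree** — branch-order assignment (penetrating arteriole = order 0
   through ascending venule = order 8), cell positioning on the tree, and
   vessel-width measurement at vessel-only (VO), pericyte (P), CAM and PEM
   landmarks;
4. **track** — cross-day cell matching, PEM retention, and gain/loss event
   detection;
5. **intensity** — marker-intensity quantification (plane projection,
   rolling-ball-style background subtraction, expanded-ROI means) compared
   by PEM status;
6. **synthetic scenes** — a generator that produces microvascular networks,
   cell placements, longitudinal series and intensity stacks with known
   ground truth, serving as the test bed for everything above.

## The association model

All coordinates are continuous micrometres, 0-based at the ROI corner,
with z increasing along the imaging depth. The criteria live in one object:

```{r}
association_criteria()
```

- `r_assoc = 10` µm: the association radius for both CAM (distance from
  the reference center to the nearest *eligible* vessel centerline) and
  PEM (distance to the nearest eligible pericyte nucleus center). The
  inequality is strict (`< 10`); ties at exactly 10 µm are a measure-zero
  event and the flag is configurable.
- `d_vessel_max = 10` µm: vessels (and the pericytes residing on them) are
  eligible only where the local diameter, interpolated at the foot point
  of the projection, is below this cap. A microglia with no eligible
  vessel anywhere is simply not a CAM — this is a signalled condition, not
  an error.
- `use_nucleus_center`: fixed-tissue analyses reference nucleus centers;
  longitudinal in-vivo analyses reference soma centers. Both centers are
  carried on every record.
- CAM and PEM labels are independent: a cell can be either, both, or
  neither. Ties between equidistant pericytes break to the lowest cell id
  for reproducibility.
- Vessel distance is measured to the *centerline*, not the wall. The
  point-to-polyline computation is exact for piecewise-linear centerlines,
  which the test suite verifies against a dense (0.1 µm) resampling
  oracle.

Three counting protocols mirror common section-based workflows: a single
800 × 600 µm box whose edge-touching nuclei are excluded (a configurable
3 µm nucleus radius decides "touching"); a 400 µm grid counting every
second complete tile; and a 500 µm grid over a region trace shrunk inward
by 50 µm, counting every fourth complete tile. Grid membership is half-open
(`[x, x + s)`), so a cell on a shared margin belongs to exactly one tile —
the one whose top or left margin it touches.

## The chance model

`simulate_chance_pem()` repositions the microglia uniformly at random in
the ROI and recomputes the PEM percentage per iteration. Two placement
modes are first class, because the appropriate null is genuinely
debatable: the default conditions on the observed pericyte pattern
(pericytes fixed — the more conservative null, since pericyte positions
encode vessel residence), while `"uniform"` repositions both populations.
Edge handling is `"clipped"` by default (points uniform in the ROI,
associations evaluated as-is); a `"toroidal"` mode wraps distances so edge
effects vanish, which is what the analytic oracle assumes:

$$P(\text{PEM by chance}) = 1 - e^{-\lambda_p \pi r^2} \quad (2D), \qquad
  1 - e^{-\lambda_p \tfrac{4}{3}\pi r^3} \quad (3D),$$

the probability that a uniformly placed point has at least one neighbour
within $r$ under a homogeneous Poisson process of intensity $\lambda_p$.
The test suite holds the simulation to this closed form within Monte-Carlo
error across $\lambda_p \in [10^{-6}, 10^{-4}]\,\mu m^{-2}$, and checks
the $1/\sqrt{n}$ scaling of the Monte-Carlo standard error. The default
iteration count (1000) keeps the standard error of a ~1.5% proportion over
~100 microglia an order of magnitude below reporting precision.
`enrichment_report()` pools replicate (observed, expected) pairs, reports
per-replicate ratios and the fold enrichment of pooled means, and
delegates the paired comparison to `stats::wilcox.test`.

## The vascular tree and width measurement

Branch orders follow the arteriole-to-venule taxonomy: the root
(penetrating arteriole) is order 0, every junction increments the order by
one, and the ascending venule terminates the default tree at order 8. The
traversal is a hand-rolled breadth-first walk (cycles are refused unless a
spanning tree is requested); the tests compare it against an independent
line-graph BFS oracle on random trees. Both endpoints of the root segment
sit at depth 0, so a capillary branching off either end of the arteriole
is first order.

Width rules encode the measurement conventions:

- P and PEM widths are taken at the pericyte soma; in fixed mode as the
  mean of two lines drawn at ±4 µm on either side of the soma (the soma
  is ~5-6 µm across, so 4 µm clears it), in in-vivo mode as a single line
  at the center. Both rules are implemented and mode-selected because the
  two imaging contexts use different conventions.
- CAM width is measured at the soma's projection onto its nearest eligible
  vessel, and only for CAM farther than 10 µm from every pericyte, to
  avoid contaminating the CAM set with PEM.
- VO (vessel-only) points require no pericyte or microglia soma within a
  10 µm clearance radius.
- Every measurement must sit more than 10 µm of arclength from a junction
  node (branchpoint exclusion — the excluded distance is not stated by
  measurement protocols that simply avoid branchpoints, so it defaults to
  the one length scale the criteria already use) and on a vessel below
  10 µm diameter.
- Per-group (animal/scene) means require at least 4 measurements per
  location type (2 for gain/loss event pairs); groups below threshold are
  excluded and reported. The omnibus comparison is delegated to
  `stats::friedman.test`.

## Longitudinal tracking

`match_across_days()` links same-type cells across consecutive days by
greedy mutual-nearest-neighbour matching within a 15 µm displacement
tolerance (ties break by distance then id). In the regime the data occupy
— displacements far below inter-cell spacing — this equals the globally
optimal assignment, which the tests verify by exhaustive enumeration on
small instances. The tolerance is exposed rather than fixed because no
standard value exists for deciding two detections are "the same" cell.

`pem_retention()` reports, per follow-up day, the fraction of day-0 PEM
whose tracked microglia is still within the association radius of *any*
pericyte (the wording of the retention concept), alongside the stricter
same-partner variant. A day-0 PEM whose microglia cannot be matched on a
later day counts as not retained — the conservative convention a manual
tracker would use. `gain_loss_events()` tracks each pericyte's has-PEM
status across days and classifies the sequence stable / gained / lost /
transient, feeding the paired width-change analysis.

## Intensity quantification

The marker workflow mirrors a two-projection convention: outlines are
traced on a max projection, quantification runs on a sum projection of the
same planes (8 planes of 1 µm by default, covering a pericyte soma).
Background subtraction implements the rolling-ball estimate as a grayscale
morphological opening with a disc structuring element of the same radius
(50 px default) — a documented approximation of the classic algorithm; the
contracts held in tests are the ones that matter for the downstream
statistics: a constant image maps to zero, sub-radius blobs survive within
5%, and larger radii never degrade blob preservation. ROI membership uses
the pixel-center rule, and the 0.25 µm ROI expansion is a Euclidean offset
in physical units (a pixel joins the expanded ROI when its center is
inside the polygon or within 0.25 µm of its boundary), not a pixel
dilation. Images are floating-point throughout. The with-PEM versus
without-PEM comparison is a paired t-test over per-scene group means.

## The synthetic-scene generator

The generator is first-class, tested code; its defaults *are* the study
conditions everything else is validated under.

- **Geometry**: a 210 × 210 × 130 µm field (a two-photon imaging volume);
  one arteriole-to-venule path (orders 0-8) plus budgeted side
  bifurcations up to order 7. The segment budget (48 segments of 40-80 µm)
  keeps total capillary length — and with it pericyte counts and the
  chance level — stable across seeds; growth reflects off the ROI walls so
  every centerline point stays inside. Baseline diameters are 15 µm
  (arteriole), 4.21 µm (capillaries — the observed cell-free capillary
  width) and 12 µm (venule), with 2% multiplicative point noise.
- **Pericytes**: anchored at uniform arclengths on capillaries with a
  25 µm minimum spacing (pericyte somata are sparse, isolated bumps), at
  0.0083 per µm of centerline. That density is the chance-level
  calibration: it puts the probability that a uniformly placed microglia
  falls within 10 µm of a pericyte near 1.5%.
- **Microglia**: 1.4 × 10⁻³ per µm² of footprint. This is denser than
  tissue (where ~100 cells/mm² is typical); the choice trades realism of
  the per-scene count for statistical power, making one scene the
  equivalent of several pooled replicates. A configured fraction is
  vessel-attracted (0.25; placed within 8 µm of a centerline point sampled
  clear of pericyte somata, so this class cannot be PEM by construction)
  and a fraction pericyte-attracted (0.064; placed within 8 µm of a
  pericyte nucleus, hence PEM by construction since 8 < 10). Together with
  the chance floor these put the scene-level PEM proportion near 7% — a
  roughly five-fold enrichment — and the CAM proportion near 40%.
- **Landmark dilation**: vessel diameter is dilated multiplicatively over
  a ±5 µm arclength window at cell landmarks, by the realized geometry
  (not the placement intent): 1.16 at a pericyte, 1.21 at a pericyte with
  a PEM, 1.15 at a CAM clear of pericytes. Overlapping windows take the
  maximum factor rather than stacking.
- **Time series**: per visit, each adjacency persists with the per-visit
  retention schedule (default 0.810, 0.963, 0.564 across days 0-4, 4-7,
  7-28 — cumulative 81% / 78% / 44%); retained microglia re-settle within
  the attraction ball, lost microglia are displaced beyond the association
  radius with an extra margin (2 jitter SDs + 2 µm) so losses remain
  unambiguous as cells keep jittering (stable-cell jitter SD 3 µm per
  axis; loss walk SD 15 µm). Pericytes without a PEM gain one with
  probability 0.12 per visit, recruiting a free microglia outside the
  day-0 PEM population so gained associations are genuinely new. Gains
  multiply the local diameter by 1.20, losses by 0.91, and every event is
  logged with its day stamp.
- **Intensity stacks**: Gaussian soma-scale blobs (SD 3 µm) around a
  configurable subset of pericytes, a smooth background field, flat offset
  and additive noise, with per-pericyte ground-truth added intensity
  recorded.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis assumes: known
association geometry, Poisson-like null placement, calibrated enrichment,
a branching tree with labelled orders, localized width changes, Markovian
retention dynamics, and blob-plus-background images. It does **not**
emulate cell morphology (processes, ramification), photorealistic optics,
hemodynamics, segmentation errors, registration drift between sessions, or
mural-cell subtypes beyond class labels. Passing tests therefore
demonstrate that the pipeline recovers known truth under the stated
statistical assumptions — not that those assumptions hold in any given
real data set.

One structural property deserves emphasis: because pericytes live on a
one-dimensional vessel network, their planar pattern is *clustered*, never
completely spatially random. The nearest-distance distribution from
uniform microglia to generated pericytes therefore does not follow the
Poisson nearest-neighbour law at any achievable density (we measured
Kolmogorov-Smirnov distances of 0.19-0.44 against it across regimes). The
suite instead verifies (a) that null-regime microglia are statistically
indistinguishable from uniformly re-placed microglia against the *actual*
pericyte pattern — which is precisely the null the chance module
conditions on — and (b) the Poisson law itself on both-uniform placement
under the toroidal metric, where it holds exactly. This is also why the
default chance null keeps pericytes fixed.

## Numerical choices and degenerate inputs

- Distances use the exact segment-projection formula; eligibility is
  re-checked at the foot point when a piece's diameter straddles the cap.
- Zero denominators (no microglia, no CAM, no pericytes on a day) yield
  missing values, never zero.
- An ROI too small for an arteriole-to-venule path, or a pericyte demand
  that cannot satisfy the minimum spacing, raise classed errors
  (`pemscope_infeasible_geometry`, `pemscope_infeasible_density`).
- Empty slabs, empty link tables and event-free series are valid empty
  results.
- All randomness flows through R's single RNG stream, seeded once per
  top-level call; identical config and seed reproduce scenes, simulations
  and stacks bit for bit.
- Multiple-testing correction is not applied by default (per-comparison
  p-values are reported); it can be layered on by the caller.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
scenes at desk scale, chosen so the full suite completes in minutes on one
CPU: unit scenes of ~50-150 cells and ~50 segments; 100-seed batches for
null self-consistency; 50-seed batches for enrichment, retention and width
recovery; 5000-iteration Monte-Carlo runs for the analytic-oracle
comparison; 400-seed batches for density calibration. Each batch size was
picked so the statistical tolerance being asserted (for example, three
standard errors of a Monte-Carlo mean, or binomial confidence-interval
coverage over 50 replicates) is comfortably resolvable at that n.

## Known limitations

- The generator's microglia density is inflated for power (see above);
  per-scene counts are not tissue-realistic.
- SWC export merges polylines into sample chains; branch orders are not
  representable in SWC and must be re-assigned after import.
- The rolling-ball approximation is a grayscale opening; byte-level
  agreement with any specific image-analysis application is out of scope.
- Process-level (non-soma) contacts, image segmentation and registration
  are out of scope; inputs are assumed to be registered coordinate
  exports.
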