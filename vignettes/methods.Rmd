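---
title: "Methods: sarcomere integrity and YAP1 localization scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sarcomere integrity and YAP1 localization scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

Tyrosine-kinase inhibitors such as sunitinib disrupt the contractile
apparatus of human iPSC-derived cardiomyocytes. In healthy cells,
alpha-actinin immunofluorescence shows sarcomeric Z-lines as regular
parallel stripes; in injured cells the staining collapses into dot-like
puncta. `sarcscreen` turns this qualitative phenotype into per-well
numbers suitable for dose-response inference:

1. **Per-cell Z-line length.** Every curvilinear alpha-actinin component in
   a cell is measured; the cell's summary is the arithmetic mean of its
   component lengths.
2. **Well-organized-sarcomere call.** A cell is "well-organized" when its
   mean Z-line length is *strictly greater* than a cutoff, 3.1 µm by
   default. Cells with no detected component never qualify, but stay in
   the denominator.
3. **Healthy Sarcomere Index (HSI).** The fraction of well-organized cells
   among all cells of a well, reported as percent of the vehicle-control
   group mean (ratio of group means, so control is exactly 100%).
4. **YAP1 nuclear localization.** In the low-magnification branch, a cell
   counts as nuclear-localized when its background-subtracted
   nuclear/cytoplasm mean-intensity ratio exceeds a threshold (default
   1.3); the per-well index is the fraction of measurable cells.

Wells, not cells, are the statistical unit: each well contributes one HSI
or YAP-index value, and groups of 5–6 wells are compared.

# Imaging model and segmentation

The commercial analyzer software behind the original assay is a black
box, so the segmentation chain is built from standard, reproducible
morphology (EBImage):

* **Nuclei**: Gaussian smoothing (σ = 1 µm), Otsu threshold, hole fill,
  distance-transform watershed (tolerance 2) to split touching nuclei,
  and a 25 µm² minimum-area filter. Cells are treated as mononuclear, so
  the nucleus count is the cell count; per-well counts are sums over the
  well's fields.
* **Territories**: marker-positive foreground (Otsu on the smoothed
  marker channel, union the nuclei) is partitioned by seeded propagation
  from the nucleus labels. Exactly one territory per nucleus; territories
  are disjoint by construction.
* **Z-lines** (60× branch): white top-hat sized to the nominal Z-line
  width (0.8 µm) enhances the striations; Otsu within territory
  foreground binarizes them; each connected component is thinned
  (Zhang–Suen) and measured as the longest geodesic path through its
  skeleton (orthogonal steps 1 px, diagonal √2), which is the natural
  discrete estimator for a curvilinear structure. Branch points are
  treated as noise fusions: only the longest path counts, never total
  skeleton mass. Thinning erodes roughly half the stripe width off each
  end, so the end caps are restored from the component area by solving
  area ≈ (path + w)·w for the width w. Components shorter than 0.5 µm are
  discarded as noise, components touching the field border are excluded
  (configurable), and each segment is assigned to the territory containing
  its centroid — cheap, deterministic, and tie-free. On isolated synthetic
  stripes of 1–8 µm this estimator is accurate to better than two pixels
  at 0°, 45° and 90°.
* **YAP1 intensities** (4× branch): nuclear mean over nucleus pixels;
  cytoplasm mean over the territory minus the nucleus dilated by 1 px; a
  background estimate (median of non-territory pixels by default) is
  subtracted from both. Cells with an empty cytoplasm region are flagged
  unmeasurable and leave the index denominator.

Coordinates are pixel-centred, origin top-left, row-major; all reported
lengths are in µm.

# The statistical layer

Dose groups are compared to control with one-sided step-down trend tests
at α = 0.025, assuming a monotone dose effect (decreasing for toxicant
endpoints; increasing for rescue-versus-sunitinib comparisons, which must
be declared per endpoint):

* **Gate.** Bartlett's test across all groups at α = 0.05 chooses the
  test: homogeneous variances → Williams' test on the observations;
  heterogeneous → the rank-based Shirley–Williams analogue. If every group
  is constant and equal the equal-variances convention keeps Williams';
  a zero-variance group among variable ones falls back to the rank test
  with a warning. The gating test and its level are assumptions exposed in
  the interface, as is the one-sided direction.
* **Williams' test.** At step *j* (starting from the highest dose) the
  statistic is the amalgamated (isotonic, pool-adjacent-violators) mean of
  dose *j* minus the control mean, over the pooled-variance standard
  error. Stepping down stops at the first non-significant dose, which
  makes significance coherent in dose by construction.
* **Shirley–Williams.** The control and the doses still in play are
  re-ranked jointly at every step (midranks for ties, tie-corrected rank
  variance); otherwise the same amalgamation and step-down logic. It is
  invariant under strictly increasing transforms of the data.
* **Critical values.** Rather than transcribing the historical tables,
  critical values are the (1 − α) quantiles of the step statistic under a
  seeded standard-normal Monte-Carlo null (100,000 replicates, cached per
  design), which covers unbalanced designs uniformly. At k = 1 the
  closed-form one-sided Student-t quantile is returned, and the
  Monte-Carlo machinery is validated against it. The rank test uses the
  same critical values with infinite degrees of freedom, the classical
  pairing. Simulated familywise error at α = 0.025 lands near nominal
  (about 0.023 for Williams under a normal null, about 0.022 for
  Shirley–Williams under a Cauchy null, 10,000 replicates each); the
  rank statistic is discrete at n = 6, so its attained size sits slightly
  below nominal.
* **Two-group comparisons** (α = 0.05, two-sided): Student's t with
  pooled variance when an F-test at 0.05 accepts homogeneity, otherwise
  the Wilcoxon rank-sum test; a zero-variance group forces the rank test
  because the F-test is undefined there.

The cutoff search (`optimize_cutoff`) scans a grid (default 1.0–6.0 µm,
step 0.1) for the value maximizing the Youden-style separation
`frac_control(c) − frac_positive(c)` under the same strict `>` rule used
for scoring, breaking ties toward the smaller cutoff. It is an auxiliary
tool: the default pipeline keeps the fixed 3.1 µm rule.

# The synthetic-plate generator

No reference images ship with the assay, so every stage is exercised on
synthetic plates with exact ground truth. The generator emulates the
imaging design: 9 fields/well at 60× (0.25 µm/px, 512×512, ~22 cells per
field, ≈200 cells/well) for sarcomere morphology, and 6 fields/well at 4×
(1.6 µm/px, 720×720, ~667 cells per field, ≈4000 cells/well) for YAP1.
Pixel sizes are package choices: they resolve Z-lines at 60× and match
the field-of-view/cell-count arithmetic at 4×.

Cells are mononuclear, placed by Poisson-disc (dart-throwing) sampling
with a minimum centroid spacing (12 µm at 60×, 29 µm at 4×) so nuclei
remain separable while footprints may touch, as in real monolayers; the
generator raises an error when a field cannot host the requested count at
that spacing. Healthy cells render as parallel anti-aliased stripes with
1.9 µm sarcomere periodicity inside an elliptical footprint, with
per-segment true lengths drawn from a truncated normal (default mean
5.0 µm, sd 0.5); disrupted cells render 20–30 short puncta (mean 1.0 µm,
sd 0.25). These distributions are placeholders chosen to straddle the
3.1 µm cutoff — the real per-cell length distribution is unknown — so
parameter-recovery results certify the measurement chain, not the
biology. YAP cells carry a cytoplasmic intensity with the nucleus region
at `ratio ×` that intensity, the true ratio drawn per cell (nuclear
population mean 2.0, cytosolic 0.95 against the 1.3 threshold). Camera
noise is Poisson shot noise plus Gaussian read noise (sd 3) over a
constant background (100), stored as 16-bit TIFF.

Determinism: each (well, field) renders under a substream seed derived by
a fixed hash of the master seed, so plates are byte-reproducible and
independent of evaluation order.

What the generator deliberately does **not** model: point-spread blur,
z-stacks, channel bleed-through, multinucleation, edge-clipped cells,
beating motion, or staining artifacts. Passing recovery tests therefore
demonstrate that the chain measures what the image formation draws — they
do not certify performance on real microscope data, where the threshold
and size parameters in `seg_params()` would need adjustment.

# Scenario presets and their severities

Three presets mirror the screening designs: `dose_response` (control plus
0.3/1/3 µM sunitinib with healthy fractions 1.0/0.65/0.15/0.01),
`washout_recovery` (independent plates at 0/72/144 h with severities
relaxing to control: 0 h as above, 72 h = 1.0/0.85/0.70/0.20, 144 h all
1.0 — cells are fixed for imaging, so timepoints are independent plates),
and `rescue_cotreatment` (control, 1 µM sunitinib alone at 0.15, plus
XMU-MP-1 co-treatments at 0.45 and 0.65, tested in the increasing
direction against the sunitinib-alone group). The severities reproduce
each design's qualitative ordering — strong dose-dependent disruption,
full recovery after washout, partial rescue — and are explicitly not
calibrated to any measured plate.

# Numerical choices and degenerate inputs

* All-flat or noise-only images yield zero nuclei, not an error; wells
  with zero cells are dropped with a warning; wells under 50 cells are
  flagged low-count.
* A territory with no detected Z-line component gives an undefined mean
  length (`NA`); such cells count in the denominator only.
* The YAP ratio floors the cytoplasm mean at a small positive constant;
  unmeasurable cells leave the denominator.
* Otsu thresholds are computed on 256-bin histograms; a near-constant
  intensity range short-circuits to "no objects".
* Trend statistics with a zero standard error (all-constant data) are
  defined as 0, hence never significant.
* Monte-Carlo critical values restore the caller's RNG state, so calling
  the trend tests does not perturb user-level reproducibility.

# Problem sizes used by the test-suite

The packaged checks run the plate designs at their native sizes — the
4-group × 5-well × 9-field sarcomere plate (~200 cells/well) and the
2-group × 6-well × 6-field YAP plate (~4000 cells/well) — and the
operating characteristics of the trend tests on 10,000-replicate nulls
(3,000 replicates for the power check). Unit fixtures use smaller plates
(1–2 wells, 2–4 fields, reduced cell densities) chosen to exercise the
same code paths at interactive speed.

# Known limitations

* Segment-to-cell assignment by centroid membership mis-assigns the rare
  segment whose centroid falls just outside its generating territory;
  on synthetic fields over 95% of segment pixels land in the correct
  territory.
* The skeleton length estimator is least accurate for diagonal stripes
  (up to ~1.7 px error), still inside the two-pixel contract.
* The attained size of the rank trend test inherits rank discreteness at
  n = 5–6 wells; its familywise error is slightly conservative.
* Percent-of-control uses the ratio of group means; with very small
  control means the ratio is unstable, and a zero control mean is an
  error by design.
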