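---
title: "Compartmental zonation of spatial transcriptomics spots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental zonation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotzoner)
```

## The problem

In tissue sections that contain two sharply distinct compartments — the
motivating case is mouse liver bearing colorectal metastases — the biology of
interest is often organized by *distance to the compartment boundary*: the
tumor margin is the most immune-active region, while the tumor core is
immunosuppressed. Spot-based spatial transcriptomics (10x Visium, ~100 um
spot pitch; Visium HD, 2-16 um bins) samples this organization on an integer
array lattice. `spotzoner` converts a binary per-spot tissue label
(`tissue_class`: 1 = tumor/metastasis, 0 = parenchyma) into an ordinal
*compartmental zone* for every spot — by default eight zones, `Zone_A`
(inner tumor) through `Zone_H` (distant parenchyma) — and provides the
downstream statistics that are computed per zone.

## The zonation model

For one sample, the spots are rasterized onto the bounding box of their
array coordinates. Three aligned lattices are built: a tumor indicator
(1/0), its complement, and a barcode lookup; lattice positions not covered
by a spot (off-tissue positions, and the unoccupied checkerboard positions
of the hex-packed Visium array) are missing.

The core primitive is a *missing-aware square moving average*. For window
half-width $\delta$, the smoothed value at cell $(i,j)$ is the arithmetic
mean of the non-missing cells in the $(2\delta+1)\times(2\delta+1)$ window
centered there, with the window clipped at the lattice borders. A tumor
indicator smoothed this way measures the local tumor fraction: deep inside
the tumor it is 1, at a straight boundary it is about 1/2, and it decays
with distance on the other side.

Two window sizes are combined into a composite boundary-distance score.
With tumor indicator $T$:

$$ S_{tum} = \left[\, w_1 \cdot \mathrm{MA}(T, \delta_1) + w_2 \cdot
   \mathrm{MA}(T, \delta_2) \,\right] \cdot T $$

and symmetrically for the parenchyma indicator $P = 1 - T$ with its own
weights. The trailing multiplication masks the score to its own
compartment, so every occupied cell carries a positive score on exactly one
side. With the defaults $\delta_1 = 2,\ \delta_2 = 3$, tumor weights
$(2, 1)$ and parenchyma weights $(2, 0.1)$, the tumor score lies in
$(0, 3]$ on tumor spots and the parenchyma score in $(0, 2.1]$ on
parenchyma spots, the maxima being attained exactly when both windows
contain only the spot's own tissue.

Scores are thresholded into ordinal zones with half-open intervals
$(\mathrm{lo}, \mathrm{hi}]$. Tumor cuts $M_1 = 2.96 > M_2 = 2.7 > M_3 =
2.3$ give ordinals $-4$ ($s > M_1$) through $-1$ ($0 < s \le M_3$);
parenchyma cuts $L_1 = 2.095 > L_2 = 1.91 > L_3 = 1.7$ give $0$
($0 < s \le L_3$) through $3$ ($s > L_1$). Because the masks make the two
ordinals mutually exclusive, their sum spans $-4 \dots 3$ and indexes the
eight zone names in order. The cuts were chosen so that each intermediate
zone is about one spot layer (~100 um on Visium) thick; supplying $k$ tumor
and $m$ parenchyma cuts with $k + m + 2$ names yields finer zonations.

### Numerical and boundary behavior worth knowing

* **Missing cells are ignored, never zero-filled.** A window mean is taken
  over its observed cells only; a window with no observed cell is missing.
  This is what makes the square window meaningful on the hex lattice, where
  roughly half of the positions are structurally unoccupied.
* **Edges clip.** The default window is truncated at the lattice border and
  the mean is over in-bounds cells (so a uniform grid scores its maximum
  everywhere, including corners). `edge_policy = "missing"` is available to
  blank the border band instead.
* **Intervals are half-open from above**, matching the sequential
  "overwrite values above the cut" formulation: a score exactly at a cut
  belongs to the zone *below* it. The interval-based assignment is
  property-tested against a literal sequential-overwrite oracle.
* **Joins are by `(sample_id, barcode)`**, never by row or matrix order,
  and coordinates are kept with explicit offsets, so 0-based Visium
  coordinates and arbitrary translations are safe. An unmatched barcode is
  an error, never a silent default zone.
* **Per-sample independence.** Windows are computed one sample at a time;
  smoothing never crosses samples.
* On idealized straight-boundary geometry the parenchyma score jumps from
  about $1.67$ to about $2.09$ between the first and second parenchyma
  layers, so `Zone_F` $(1.7, 1.91]$ is empty there. This is a property of
  the default cuts on perfectly regular geometry; irregular boundaries and
  the hex layout populate it. We kept the published constants rather than
  retuning them.

## Worked example

```{r zonate-example}
spots <- expand.grid(array_row = 1:30, array_col = 1:30)
spots$barcode <- sprintf("BC%03d_%03d", spots$array_row, spots$array_col)
spots$tissue_class <- as.integer(spots$array_col <= 15)
res <- zonate_sample(spots)
table(res$table$zone)
res$tumor_score$values[15, 13:16]
```

## Downstream statistics

* `zone_group_key()` concatenates treatment group and zone
  (`parRes_Zone_B`); this combined label is the unit of differential
  expression.
* `wilcoxon_one_vs_rest()` tests every gene in each label against all
  remaining spots. The p-value uses midranks with the tie-corrected normal
  approximation and no continuity correction, except that both sides having
  at most 8 spots triggers exact enumeration of the rank-sum distribution
  (the approximation is unreliable in the tails at such sizes). The fold
  change is `log2((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))` on
  log-normalized values — the convention differs between versions of the
  popular single-cell toolkits, and this de-logged-mean pseudocount-1 form
  is the one documented here and used consistently. `pct` columns count
  spots with any expression (> 0). Benjamini-Hochberg adjustment is applied
  within each label.
* `module_score()` implements expression-matched signature scoring: genes
  are binned into `nbin = 24` equal-frequency bins by mean expression; each
  signature gene draws `nctrl = 100` controls from its bin (with
  replacement if the bin is small); the score is mean(signature) −
  mean(controls). The seed is a required argument — there is no hidden
  default — and binning/draws are resolved in gene-name order so the score
  does not depend on matrix row order.
* `gene_fc_summary()` and `signature_median_summary()` produce the per-zone
  median tables (`FC = 2^avg_log2FC`; medians per gene/signature x zone x
  group with per-name minima) used for zonation profiles.
* QC follows the protocol defaults: keep spots with strictly more than 500
  detected genes and strictly less than 20% mitochondrial counts
  (`qc_params(inclusive = TRUE)` switches to inclusive comparisons, since
  prose and code traditions differ on this). Normalization is
  `ln(1 + 1e4 * count / spot_total)`; the upstream variance-stabilizing
  transform of the original workflow is deliberately not reproduced, and
  all scoring here operates on log-normalized values.

## The synthetic generator

`simulation_spec()` describes the emulated study conditions; the defaults
are fixed once and mirror a standard Visium experiment: a hex-packed
78 x 128 lattice (~5,000 spots at 100 um pitch), a disk-shaped metastatic
region, and eight samples across the three treatment groups
(Ctrl / nonRes / Ctrl / parRes / parRes / nonRes / Ctrl / parRes). Counts
are negative binomial (`size = 2`) around lognormal library sizes (mean
10,000, sdlog 0.35, typical of Visium liver sections), with marker
programs at 8-fold enrichment, `mt-` genes at 10% of the library, and
gradient genes spanning 2 log2 units across the boundary distance. Label
noise is applied at the label level (`label_flip_prob`), not the
expression level, so geometry tests stay exact; the true region membership
and the signed Chebyshev distance to the boundary are recorded as ground
truth.

What the generator does *not* emulate: spatial autocorrelation of library
size, bleed-over between adjacent spots, segmentation errors correlated
along the boundary, batch effects between samples, and dropout beyond what
the negative binomial implies. Passing tests therefore demonstrate that the
algorithmic pipeline is correct and internally consistent, not that the
default thresholds are optimal for any particular real tissue.

Tests and examples run on reduced lattices (roughly 15x15 to 40x40, 40-200
genes); these sizes were chosen because every geometric property being
checked is already fully expressed at one to two window widths, and the
statistical checks are sized to their fixtures.

## Design choices that were genuinely open

* **Missing-value semantics of the moving average** are not pinned down by
  the upstream description; ignore-missing means are the only choice that
  gives sensible values on the hex lattice, and an all-missing window stays
  missing.
* **Coordinate base:** grids cover the observed `[min, max]` coordinate box
  with recorded offsets instead of assuming 1-based positions, which would
  silently mishandle row or column 0.
* **HD barcodes** are parsed as `<prefix><col>_<row>[-suffix]` (column
  first), with a configurable prefix such as `s_016um_`; the generator
  emits the same scheme so the round trip is testable.
* **Signature-based tissue labeling** (`label_spots_by_signature()`) is
  provided as plumbing for users without cluster-derived labels: a spot is
  called tumor when the mean log-normalized expression of the tumor marker
  set exceeds the parenchyma set, with ties going to parenchyma. It is not
  a substitute for reviewing labels on real data.
* **More than 8 zones** are supported by supplying more cuts and names;
  the mapping generalizes to `k + m + 2` zones.

## Limitations

The method presumes the two compartments are distinguishable per spot and
that a binary label is available or derivable; fuzzy transitions are forced
into the binary label before smoothing. Zone thickness is tied to the spot
pitch — on Visium, sub-100 um zonation is not meaningful, while on Visium
HD more zones and larger deltas are appropriate. Distances are lattice
(Chebyshev-window) distances on array coordinates, not geodesic distances
in tissue space.
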