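---
title: "Quantifying blue-light damage in skin models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blue-light damage in skin models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digistress)
```

This vignette explains the models behind each quantification stage, the
parameters that matter, the numerical conventions, and what the synthetic
data do and do not emulate.

## Mitochondrial network metrics

### The skeleton graph

A mitochondrial fluorescence image is segmented by Otsu's threshold after a
light Gaussian blur (default sigma 0.5 px — enough to suppress shot noise
without widening filaments into their neighbors), thinned with two-pass
Guo–Hall parallel thinning, and decomposed into a node/edge graph. Pixel
classification uses the 8-neighbor count of the one-pixel-wide skeleton:
endpoints have one neighbor, junction pixels three or more, isolated pixels
none. Adjacent junction pixels are merged into a single junction-cluster
node; without this merge every T- or X-crossing of a rasterized filament
would split into several spurious junctions and inflate branch counts.
Branches are pixel paths delimited at each end by a junction or an
endpoint; trees are the connected components; an isolated pixel is a
zero-length tree, and a closed pixel cycle without any node is one tree
with a single closed branch.

### Length conventions

On a raster there is no unique filament length; we use the standard
chain-code metric: an axial step counts 1 pixel, a diagonal step sqrt(2)
pixels, scaled by the pixel size in um. Two consequences are handled
explicitly:

* **Tip erosion.** Parallel thinning shortens line ends by about one
  pixel. Skeleton tips are therefore re-extended along their local
  direction while they remain inside the binary mask and touch no other
  skeleton pixel; an 11-px medial axis of a solid bar is recovered
  exactly.
* **Junction clusters.** Steps between two pixels of one junction cluster
  belong to the node, not to any branch. Each branch that meets a cluster
  is extended from its attachment pixel to the cluster centroid, so the
  cluster-internal length is apportioned to its branches and the
  conservation law (sum of branch lengths = tree length; sum of tree
  lengths = network total length) holds to numerical precision.

With zero trees the total length is 0 and all ratio metrics are reported
as missing, never as zero.

### The independent census

`build_graph()` walks pixel paths; `skeleton_census()` reaches the same
quantities by a different route entirely — it builds the explicit
pixel-adjacency graph in igraph, takes components for trees, components of
the degree-2 subgraph for branch interiors, and components of the
degree>=3 subgraph for junction clusters. The two routes must agree
*exactly* (counts and lengths) on every input; the test suite asserts this
on a fixture set of hand-checkable rasters (lines, T, Y, plus, rings, a
diamond cycle, disjoint pieces, an isolated pixel) and on randomly thinned
blobs. Keeping both routes in the package means any future change that
breaks one convention is caught immediately.

### Open choices

The tree/length and branch/length ratios can be formed per cell and then
averaged, or from per-well means; both are available (`aggregate_well()`
averages the per-cell ratios unweighted, and the per-well means of the
numerators and denominators are in the same table). Short-spur pruning
before branch counting is deliberately **off** by default: heavily
fragmented networks are dominated by short trees, and discarding specks
would bias the trees-per-length statistic that carries the stress signal.

## The mitochondrial generator

One synthetic image is one cell: a disk (default radius 42% of the field)
in which `n_trees = 1 + Binomial(max_trees - 1, fragmentation)` trees are
grown, so fragmentation 0 forces exactly one tree and the expected tree
count rises linearly while the total length budget (default 450 um, the
scale of an unstressed fibroblast network) stays fixed — fragmentation is
a purely topological dial, matching how the stress phenotype is described
(many short trees rather than less dye).

Trees must not touch, or the analysis could not count them; each tree is
confined to the Voronoi territory of its site (farthest-point site
sampling; the length budget is split in proportion to territory area).
Within its territory a tree grows as a branching reticulum: structural
segments of 20–45 um are attached at random interior vertices of the
existing structure, plus short side branches (4–8 um, 0.08 per um of tree
length); every attachment splits the host polyline, so the stored truth
polylines are exactly the branches of the graph definition. Walks are
persistent random walks (step 2 um, turning sd 0.15 rad) that avoid a
shared occupancy grid (1.5 um cells, 3x3 neighborhood), keeping filaments
from running close enough to merge after rendering.

Rendering stamps the polylines one pixel wide, blurs with sigma = 1 px,
and applies a Poisson photon + Gaussian read-noise model (defaults: 200
signal photons, background 10, read noise sd 2; `noise = 0` yields the
clean signal). Defaults are 320x320 px at 0.3 um/px — a 96 um field at a
40x-objective scale; neither value is prescribed by the source material,
which names the instrument but not the pixel pitch.

**What recovery means here.** At zero noise the detected metrics track the
generator truth within about 10% on average (the residual bias is
rasterization, junction clusters, and rare filament merges). The
generator does not emulate uneven illumination, out-of-focus light, dye
loading variation, or 3-D network structure, so passing recovery tests
demonstrates the correctness of the measurement chain, not robustness to
real-microscope artifacts.

## Cell spreading

The micropattern generator lays sites on a grid (pattern side 90 um,
pitch 1.3 sides), each empty (5%), single (90%), or a doublet (5%). A
cell is a filled equilateral-triangle footprint whose rasterized pixel
count is corrected to the true area exactly, so area recovery is limited
only by detection. Areas are drawn from a truncated normal (default
2000 +/- 350 um^2, spanning the 1800 um^2 spread threshold). Analysis
fills holes before measuring (the spreading area is the footprint, not
the stained skeleton), assigns components to the nearest pattern center,
and excludes zero- and multi-cell sites with the reason logged. The
spread criterion is strict (area > 1800 um^2): a boundary cell does not
count, because the defining phrase is "exceeding". The percentage can be
pooled over cells or computed per well and averaged; both are emitted by
the drivers.

## Stain color index

The recipe mirrors the manual GIMP/ImageJ procedure: select stain-colored
pixels, histogram color into 255 categories, cut and sum the stain peak,
divide by the ROI surface area. Two ambiguities had to be fixed:

* "255 color categories" is implemented as 255 equal hue bins over the
  hue circle, making the histogram a pure color measure independent of
  brightness; the brightness-invariance test (scaling RGB by 0.8 leaves
  the index unchanged within one bin quantization) protects this choice.
* The denominator is the ROI area ("the dermis", supplied as a mask), not
  the selected-pixel count — the index is then exactly the stained
  fraction of the ROI, which is what the generator controls.

The default band (hue 0.78–0.96, saturation >= 0.15) covers the
violet-pink chromogen and is echoed into every output for provenance. The
generator renders the stained set as the upper quantile of a smoothed
random field — blobby like chromogen deposits — with an exact stained
fraction, so end-to-end recovery must be affine with slope 1.

## Melatonin cycle

The schedule is 8 h day / 16 h night, sampled 30 min before night onset
and 2, 5, 8 h after, for three days. The night rise is modeled as a
raised cosine over the night phase scaled by (1 - s), with the bump
normalized so that the mean over the three night sampling offsets is 1:
the within-replicate induction statistic (mean night minus baseline) then
estimates amplitude x (1 - s) without bias, exactly at zero noise.
Defaults: baseline 10, amplitude 20, noise sd 2 (assay units are
arbitrary; no absolute ELISA calibration is attempted — no quantitative
concentration scale is claimed). Day 1 is the default analysis window,
where the suppression contrast is established; comparisons route through
the nonparametric ladder by default, matching how such series are
typically tested. A paired-equal-series comparison yields p = 1 rather
than an error.

## Conversion kinetics and arithmetic

The crocin→crocetin curve is a lag-clamped logistic: zero conversion up
to the lag (66 h), sigmoidal rise afterwards, completion (crocin < 1% of
initial) at 210 h with the default rate 0.064/h. The truth satisfies
crocin(t) + crocetin(t) = crocin(0) identically; measurement noise is
multiplicative (5% CV default). `conversion_balance()` estimates the
initial concentration from the pre-conversion window (product below 0.2%
of its maximum) to damp baseline noise, flags the completion time, and
tests for a plateau via the fitted drift of the last fifth of the series
(tolerance 5%, so measurement noise does not mask a real plateau).

Molar arithmetic uses a mass-per-kg basis (mmol/kg = w/w x 1e6 / molar
mass). The published description attributes the 35% w/w content to
"crocetin" while pairing it with the crocin molar mass (976.97 g/mol) and
the result 358 mmol/kg; the arithmetic only closes with crocin, so the
implementation treats the 35% as crocin w/w and notes the wording slip.
Spectrum summaries integrate by the trapezoidal rule with interpolated
band edges, so the blue-band fraction does not depend on whether 400 and
490 nm are grid nodes.

## The statistics ladder

Shapiro–Wilk at alpha 0.05 on every group gates the route; a constant
group is a degenerate input and errors. Parametric, two groups: unpaired
t-test with pooled variance. Parametric, more: one-way ANOVA, then
Dunnett versus the reference with a single pooled variance. Nonparametric:
Kruskal–Wallis omnibus plus pairwise Mann–Whitney U versus the reference
(reported regardless of the omnibus outcome, as in the source tables), or
Wilcoxon signed-rank for paired data.

Dunnett's single-step adjusted p-values come from a Monte-Carlo simulation
of the joint null of the treatment-vs-control t statistics (shared control
mean, single pooled variance): 50,000 seeded draws, cached per design.
Monte-Carlo error at p ≈ 0.05 is about 0.001, far below the reporting
resolution; a test cross-checks the adjusted p-values against
`multcomp::glht` to 0.01. The family-wise error under the global null
calibrates to 5% within Monte-Carlo error.

Percent effects are rounded to the nearest integer, half away from zero —
the convention that reproduces the published percent annotations from
their printed condition means. Three annotations do not round consistently
from the printed means under any convention (the branch-count +46% and
-21% rows and the branch-length +31% row); they are printed-rounding
artifacts of the source summary and are documented rather than chased.
The `#` flag (p < 0.1) is kept as a trend marker; `ns` applies at and
above 0.1.

## Problem sizes and determinism

The shipped test and acceptance runs use sizes chosen to exercise every
claim at desk scale: 320x320 px cells, sweeps of 5 fragmentation levels x
10 seeds, 200 melatonin replicates, 1000-simulation null calibrations, and
a 2x30-cell end-to-end demonstration. Every generator takes a mandatory
seed and restores the caller's RNG state; identical configuration and seed
reproduce images, tables, and manifests bytewise.

## Known limitations

* 2-D only; no 3-D stacks, no spectral unmixing, no realistic PSF.
* The skeleton length metric undercounts strongly curved filaments at low
  resolution and the junction-centroid convention slightly redistributes
  length near dense crossings — both routes share the convention, so the
  census cannot catch a convention-level disagreement with *physical*
  length, only implementation errors.
* Branch-level metrics are at the resolution limit when side branches are
  only a few pixels long; the generator defaults keep side branches at
  4–8 um (13–27 px) for that reason.
* The synthetic stain background is spatially homogeneous; real sections
  carry counter-stain gradients that would require ROI-local calibration.
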