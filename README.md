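# digistress

Quantification of blue-light ("digital stress") damage and protection in
in-vitro skin models.

Chronic exposure to the 400–490 nm blue light emitted by screens stresses
skin cells: the mitochondrial network of dermal fibroblasts fragments,
micropatterned cells fail to spread, oxidized proteins accumulate in
explants, and the day/night melatonin rhythm of cyclized co-cultures is
suppressed. `digistress` implements the full quantification stack for these
readouts, together with synthetic-data generators carrying known ground
truth, so every stage is testable without microscope data.

## What the package computes

**Mitochondrial network morphology.** A fluorescence image is segmented
(Otsu), thinned to a one-pixel skeleton (Guo–Hall with tip re-extension),
and decomposed into a graph: *endpoints* (1 neighbor), *junctions* (≥ 3
neighbors, adjacent junction pixels merged into one node), and *branches*
(pixel paths delimited at each end by a junction or an endpoint; axial
steps count 1·px, diagonal √2·px, in µm). *Trees* are the connected
components. Per cell the five standard statistics are reported:

- network total length `L = Σ branch lengths` (µm)
- number of trees per network length `T/L` (µm⁻¹)
- average tree length `L/T` (µm)
- number of branches per network length `B/L` (µm⁻¹)
- average (and maximum) branch length (µm)

A second, fully independent implementation (`skeleton_census()`) enumerates
the skeleton as an explicit pixel-adjacency graph with igraph and must
agree exactly with the tracing route — this is the package's internal
oracle.

**Cell spreading.** Cells on Y-micropatterns (equilateral-triangle
envelope) are detected one per pattern site, their footprint area measured
as pixel count × pixel size², and the percentage of correctly spread cells
(area strictly > 1800 µm²) reported.

**Stain color index.** For immunostained sections, stain-colored pixels
(violet-pink hue band) are selected, hue is histogrammed into 255 color
categories, the stain-peak counts are summed, and the color index =
sum count / ROI area; conditions are expressed as a percentage of the
blue-light-stressed control.

**Melatonin cycle.** Series from the cyclized co-culture (8 h day / 16 h
night, sampled −0.5, +2, +5, +8 h around night onset) are phase-aligned;
night induction = mean night value − pre-night baseline per replicate;
blue-light suppression is estimated and conditions are compared.

**Dose, molar and kinetics arithmetic.** Cumulative exposure dose
(J/cm²), molar content (mmol/kg = w/w × 10⁶ / molar mass; crocin 976.97
g/mol, crocetin 328.41 g/mol), 1:1 molar balance of the crocin→crocetin
conversion by skin microbiota, completion time, and absorption-spectrum
summaries (λmax, blue-band integral fraction).

**Statistics ladder.** Shapiro–Wilk gate on every group, then unpaired
t-test (2 groups) or one-way ANOVA + Dunnett vs the reference with a
single pooled variance (Monte-Carlo max-|t| null), or Kruskal–Wallis +
Mann–Whitney U / Wilcoxon signed-rank for nonparametric data. Effects are
percent change vs reference; flags: `#` p < 0.1, `*` p < 0.05, `**`
p < 0.01, `***` p < 0.001.

## Worked example

```r
library(digistress)

g <- gen_mito_image(fragmentation = 0.8, seed = 7)  # stressed cell
g$truth
#> <mito_truth: 26 tree(s), 86 branch(es), total length 444.0 um, fragmentation 0.80>

round(analyze_mito_cell(g$image), 3)      # detected from the image
#>   network_total_length n_trees trees_per_length avg_tree_length n_branches
#> 1              426.958      26            0.061          16.421         84
#>   branches_per_length avg_branch_length max_branch_length
#> 1               0.197             5.083            24.616

round(truth_network_metrics(g$truth), 3)  # ground truth
#>   network_total_length n_trees trees_per_length avg_tree_length n_branches
#> 1                  444      26            0.059          17.077         86
#>   branches_per_length avg_branch_length max_branch_length
#> 1               0.194             5.163                24

percent_change(2.79, 8.79)$rounded   # stressed vs untreated avg tree length
#> [1] -68
cumulative_dose(63.75, 4)            # explant exposure schedule, J/cm2
#> [1] 255
molar_content(0.35, 976.97)          # 35% w/w crocin, mmol/kg
#> [1] 358.2022
```

The detected metrics recover the generator's ground truth (all 26 trees
found; lengths within a few percent), and the arithmetic helpers reproduce
the published summary values exactly.

The numbered scripts under `analysis/` run the full panels (network
conditions, spreading, stain recovery, melatonin cycle, kinetics,
calibration) and write their tables under `results/`.

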