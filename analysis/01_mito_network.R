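#!/usr/bin/env Rscript
# Mitochondrial-network panel: simulate four conditions spanning the
# blue-light stress phenotype (untreated, stressed, two protection levels),
# analyze every cell through the skeleton-graph pipeline, and render the
# network summary table with percent-change annotations vs the stress
# control.
#
# Writes results/mito_cells.csv, results/mito_wells.csv,
# results/mito_report.csv.

suppressPackageStartupMessages(library(digistress))

seed <- 101L
n_cells <- 20L
# fragmentation levels: unstressed networks are mostly connected; the
# stress control is heavily fragmented; protection restores connectivity
conditions <- list("untreated" = 0.1, "blue light" = 0.8,
                   "extract 0.002%" = 0.45, "extract 0.004%" = 0.2)

cfg <- demo_config(seed = seed, n_cells = n_cells)
cfg$mito$conditions <- conditions
cfg$spread$conditions <- list("untreated" = 2050, "blue light" = 1850,
                              "extract 0.002%" = 2150,
                              "extract 0.004%" = 2130)
res <- run_experiment(cfg, out_dir = "results")

cat("Per-condition well means (", n_cells, "cells each):\n")
print(res$wells[, c("condition", "network_total_length", "n_trees",
                    "trees_per_length", "avg_tree_length",
                    "avg_branch_length")], row.names = FALSE)
cat("\nNetwork report (value (+/-% flag vs blue light)):\n")
print(res$report, row.names = FALSE)
cat("\nAt a fixed total length budget the stress signature is topological:",
    "more, shorter trees (higher trees per unit length, lower average tree",
    "length); the protected conditions reverse it dose-dependently.\n")
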