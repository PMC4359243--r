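#!/usr/bin/env Rscript
# Simulate the full screen: a 419-gene ubiquitin-system library (327 ligases,
# 92 DUBs), three siRNAs per gene on separate 96-well plate sets, with 5% of
# genes implanted with a two-fold decrease and 5% with a two-fold increase
# of the damage signal. Writes the plate maps, the well-level measurement
# table, and the ground truth under results/screen/.

suppressMessages(library(hcscreen))

seed <- 2026
cfg <- screen_config()
out <- "results/screen"

message("Simulating the default screen (seed ", seed, ") ...")
sim <- simulate_screen(cfg, seed = seed)

dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_plate_map(sim$layout, file.path(out, "plate_map.csv"))
write_well_table(sim$wells, file.path(out, "well_table.tsv"))
write_run_config(cfg, file.path(out, "config.yaml"))
readr::write_tsv(sim$truth$genes, file.path(out, "truth_genes.tsv"))
readr::write_tsv(sim$truth$wells, file.path(out, "truth_wells.tsv"))
write_manifest(file.path(out, "manifest.json"), cfg, seed,
               file.path(out, c("plate_map.csv", "well_table.tsv",
                                "truth_genes.tsv", "truth_wells.tsv")))

message(sprintf(
  "Simulated %d plates / %d wells; %d genes (%d with implanted effects).",
  length(unique(sim$layout$plate_id)), nrow(sim$wells),
  nrow(sim$truth$genes), sum(sim$truth$genes$effect_delta != 0)))
message("Outputs in ", out, "/")
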