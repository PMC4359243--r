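#!/usr/bin/env Rscript
# Analyse the screen simulated in 01: subtract background wells, compute
# per-plate robust z-scores, call candidate genes (|z| >= 2 for an siRNA
# hit, >= 2 concordant siRNAs for a candidate), rank by cumulative z, and
# score recovery against the implanted truth.

suppressMessages(library(hcscreen))

src <- "results/screen"
out <- "results/hits"
if (!file.exists(file.path(src, "well_table.tsv"))) {
  stop("Run analysis/01_simulate_screen.R first.", call. = FALSE)
}
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_run_config(file.path(src, "config.yaml"))
layout <- read_plate_map(file.path(src, "plate_map.csv"))
wells <- read_well_table(file.path(src, "well_table.tsv"))
truth_genes <- readr::read_tsv(file.path(src, "truth_genes.tsv"),
                               show_col_types = FALSE)

message("Normalizing ", length(unique(wells$plate_id)), " plates ...")
res <- analyze_wells(wells, layout, cfg,
                     genes = truth_genes[, c("gene_id", "gene_class")])

write_zscore_table(res$zscores, file.path(out, "zscore_table.tsv"))
write_hit_table(res$hit_table, file.path(out, "hit_table.tsv"))
writeLines(res$report, file.path(out, "report.txt"))

perf <- evaluate_recovery(res$hit_table, truth_genes)
readr::write_tsv(perf, file.path(out, "recovery.tsv"))

message(sprintf("Candidates: %d of %d genes (%d up, %d down).",
                sum(res$hit_table$candidate), nrow(res$hit_table),
                sum(res$hit_table$candidate & res$hit_table$direction == "up"),
                sum(res$hit_table$candidate &
                      res$hit_table$direction == "down")))
message(sprintf(
  "Recovery vs truth: sensitivity %.1f%% (%d implanted), specificity %.1f%% (%d nulls).",
  100 * perf$sensitivity, perf$n_implanted,
  100 * perf$specificity, perf$n_null))
message("Tables and report in ", out, "/")
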