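#!/usr/bin/env Rscript
# Validation-experiment statistics on simulated follow-up data for the top
# down-candidate from 03: (i) knockdown confirmation by qPCR (delta-delta-Ct
# relative to GAPDH), (ii) well-level gamma-H2AX means compared by unpaired
# two-tailed t-tests with asterisk labels, (iii) single-cell intensity
# distributions summarized as box-plot statistics.

suppressMessages(library(hcscreen))

src <- "results/hits"
out <- "results/validation"
if (!file.exists(file.path(src, "hit_table.tsv"))) {
  stop("Run analysis/03_normalize_and_call_hits.R first.", call. = FALSE)
}
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026
set.seed(seed)

hits <- read_hit_table(file.path(src, "hit_table.tsv"))
top_down <- hits$gene_id[hits$candidate & hits$direction == "down"][1]
message("Validating top down-candidate: ", top_down)

## (i) qPCR knockdown confirmation: three siRNAs, ~75% knockdown emulated
## as a +2-cycle target shift, triplicate technical replicates.
ct <- dplyr::bind_rows(lapply(c("siCtrl", "si1", "si2", "si3"), function(s) {
  shift <- if (s == "siCtrl") 0 else 2
  tibble::tibble(
    sample_id = s,
    gene = rep(c(top_down, "GAPDH"), each = 3),
    ct = c(rnorm(3, 24 + shift, 0.12), rnorm(3, 20, 0.12)))
}))
rq <- delta_delta_ct(ct, top_down, "GAPDH", "siCtrl")
readr::write_tsv(rq, file.path(out, "qpcr_rq.tsv"))
message(sprintf("  qPCR: residual expression %s (RQ vs siCtrl = 1)",
                paste(sprintf("%.2f", rq$rq[-1]), collapse = ", ")))

## (ii) Treated-well means, control vs knockdown, n = 3 replicate wells:
## unpaired two-tailed t-test with the asterisk convention.
ctrl <- rnorm(3, 300, 25)
kd <- rnorm(3, 170, 25)
tt <- ttest_unpaired(ctrl, kd)
tt_row <- tibble::tibble(
  comparison = paste0("siCtrl_vs_", top_down),
  mean_ctrl = mean(ctrl), sd_ctrl = summarize_replicates(ctrl)$spread,
  mean_kd = mean(kd), sd_kd = summarize_replicates(kd)$spread,
  t = tt$t_statistic, df = tt$df, p = tt$p_value, label = tt$label)
readr::write_tsv(tt_row, file.path(out, "ttest.tsv"))
message(sprintf("  t-test: t = %.2f, p = %.4f %s", tt$t_statistic,
                tt$p_value, tt$label))

## (iii) Single-cell distributions: per-nucleus intensities for control and
## knockdown wells from the generative model, summarized as box plots.
fx_params <- model_params(sigma_plate = 0)
lib <- generate_library(n_ligases = 2, n_dubs = 0, sirnas_per_gene = 1,
                        effect_config = list(fraction_down = 0.5,
                                             fraction_up = 0,
                                             delta_magnitude = log(2)),
                        seed = seed)
lay <- layout_plates(lib, c(2, 3), 2,
                     list(n_negative = 1, n_positive = 1, n_background = 1),
                     seed = seed)
truth <- build_truth(lib, lay, params = fx_params, seed = seed)
smp <- lay[lay$content == "sample", ]
null_gene <- lib$genes$gene_id[lib$genes$effect_delta == 0]
sumtab <- dplyr::bind_rows(lapply(seq_len(nrow(smp)), function(i) {
  cells <- simulate_well_cells(smp[i, ], truth, seed = seed)
  cbind(condition = ifelse(smp$gene_id[i] == null_gene, "control",
                           "knockdown"),
        boxplot_summary(cells$signal_level))
}))
readr::write_tsv(sumtab, file.path(out, "single_cell_boxplots.tsv"))
message(sprintf("  single-cell medians: control %.0f vs knockdown %.0f (n = %d, %d cells)",
                sumtab$median[sumtab$condition == "control"],
                sumtab$median[sumtab$condition == "knockdown"],
                sumtab$n[1], sumtab$n[2]))
message("Validation tables in ", out, "/")
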