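#' Generate a synthetic siRNA screening library
#'
#' Builds an in-silico knockdown library mirroring a genome-scale ubiquitin
#' screen: a set of ubiquitin-ligase and deubiquitinase (DUB) genes, each
#' targeted by several independent siRNAs. A configurable fraction of genes
#' carries an implanted knockdown effect (an additive shift of per-cell
#' log-intensity under treatment); the rest are nulls. Each siRNA gets a
#' knockdown efficacy, the fraction of its gene's effect it realises.
#'
#' @param n_ligases,n_dubs Number of ligase and DUB genes (defaults 327 and
#'   92, the composition of a full ubiquitin-system library).
#' @param sirnas_per_gene Independent siRNAs per gene (default 3).
#' @param effect_config List with `fraction_down`, `fraction_up` (fractions of
#'   genes implanted with a negative / positive effect; the remainder are
#'   null) and `delta_magnitude` (absolute log-scale effect size).
#' @param efficacy_range Range of per-siRNA knockdown efficacies, drawn
#'   uniformly (default `c(0.6, 0.95)`).
#' @param seed Integer seed; the same seed always yields the same library.
#'
#' @return An object of class `sirna_library`: a list with tibbles `genes`
#'   (`gene_id`, `gene_class`, `effect_delta`) and `sirnas` (`sirna_id`,
#'   `gene_id`, `index`, `efficacy`), plus `sirnas_per_gene` and `seed`.
#' @export
#' @examples
#' lib <- generate_library(n_ligases = 5, n_dubs = 2, seed = 1)
#' lib$genes
generate_library <- function(n_ligases = 327, n_dubs = 92, sirnas_per_gene = 3,
                             effect_config = list(fraction_down = 0,
                                                  fraction_up = 0,
                                                  delta_magnitude = log(2)),
                             efficacy_range = c(0.6, 0.95),
                             seed = 1) {
  if (n_ligases < 0 || n_dubs < 0 || n_ligases + n_dubs < 1) {
    stop_hcs("Library must contain at least one gene (non-negative counts).",
             "parameter_error")
  }
  if (sirnas_per_gene < 1) {
    stop_hcs("`sirnas_per_gene` must be >= 1.", "parameter_error")
  }
  fd <- effect_config$fraction_down %||% 0
  fu <- effect_config$fraction_up %||% 0
  delta <- effect_config$delta_magnitude %||% log(2)
  if (fd < 0 || fu < 0 || fd > 1 || fu > 1 || fd + fu > 1) {
    stop_hcs("Effect fractions must lie in [0, 1] and sum to at most 1.",
             "parameter_error")
  }
  assert_scalar_number(delta, "delta_magnitude")

  n_genes <- n_ligases + n_dubs
  gene_id <- c(if (n_ligases > 0) sprintf("LIG%04d", seq_len(n_ligases)),
               if (n_dubs > 0) sprintf("DUB%04d", seq_len(n_dubs)))
  gene_class <- rep(c("ligase", "dub"), c(n_ligases, n_dubs))

  set.seed(well_seed(seed, "library"))
  n_down <- round(fd * n_genes)
  n_up <- round(fu * n_genes)
  effect_delta <- numeric(n_genes)
  if (n_down + n_up > 0) {
    hit_idx <- sample.int(n_genes, n_down + n_up)
    effect_delta[hit_idx[seq_len(n_down)]] <- -abs(delta)
    if (n_up > 0) {
      effect_delta[hit_idx[n_down + seq_len(n_up)]] <- abs(delta)
    }
  }
  genes <- tibble(gene_id = gene_id, gene_class = gene_class,
                  effect_delta = effect_delta)

  sirnas <- tibble(
    gene_id = rep(gene_id, each = sirnas_per_gene),
    index = rep(seq_len(sirnas_per_gene), times = n_genes)
  )
  sirnas$sirna_id <- paste0(sirnas$gene_id, "_s", sirnas$index)
  sirnas$efficacy <- runif(nrow(sirnas), efficacy_range[1], efficacy_range[2])
  sirnas <- sirnas[, c("sirna_id", "gene_id", "index", "efficacy")]

  structure(list(genes = genes, sirnas = sirnas,
                 sirnas_per_gene = sirnas_per_gene, seed = seed),
            class = "sirna_library")
}

#' @export
print.sirna_library <- function(x, ...) {
  cat(sprintf(
    "<sirna_library> %d genes (%d ligase, %d dub), %d siRNAs (%d per gene)\n",
    nrow(x$genes), sum(x$genes$gene_class == "ligase"),
    sum(x$genes$gene_class == "dub"), nrow(x$sirnas), x$sirnas_per_gene))
  cat(sprintf("  implanted effects: %d down, %d up\n",
              sum(x$genes$effect_delta < 0), sum(x$genes$effect_delta > 0)))
  invisible(x)
}

#' Arrange a library on multi-well plates
#'
#' Places each siRNA exactly once on a plate, with all siRNAs of a given
#' index confined to one plate set (so replicate siRNAs against the same gene
#' never share a plate). Every plate carries the requested negative-control,
#' positive-control and background (no-primary-antibody) wells in fixed
#' edge-column positions; the remaining wells are filled with samples in
#' row-major order. Gene order is shuffled once per screen so plate position
#' is not confounded with library order.
#'
#' @param library A `sirna_library` from [generate_library()].
#' @param plate_format `c(rows, cols)`; default `c(8, 12)` (96-well).
#' @param samples_per_plate Sample wells per plate (default 80).
#' @param controls List with `n_negative`, `n_positive`, `n_background`
#'   wells per plate (defaults 4, 8, 4; at least one background well is
#'   required).
#' @param seed Seed for the gene-order shuffle.
#'
#' @return A tibble (`plate_layout`) with one row per well: `plate_id`,
#'   `plate_set`, `well_id`, `row`, `col`, `content` (one of `sample`,
#'   `negative_control`, `positive_control`, `background`, `empty`),
#'   `sirna_id`, `gene_id`.
#' @export
layout_plates <- function(library,
                          plate_format = c(8, 12),
                          samples_per_plate = 80,
                          controls = list(n_negative = 4, n_positive = 8,
                                          n_background = 4),
                          seed = 1) {
  stopifnot(inherits(library, "sirna_library"))
  n_rows <- plate_format[1]
  n_cols <- plate_format[2]
  n_neg <- controls$n_negative %||% 0
  n_pos <- controls$n_positive %||% 0
  n_bg <- controls$n_background %||% 1
  if (n_bg < 1) {
    stop_hcs("Every plate needs at least one background well.", "layout_error")
  }
  n_ctrl <- n_neg + n_pos + n_bg
  if (samples_per_plate < 1 || samples_per_plate + n_ctrl > n_rows * n_cols) {
    stop_hcs(sprintf(
      "%d sample + %d control wells do not fit a %dx%d plate.",
      samples_per_plate, n_ctrl, n_rows, n_cols), "layout_error")
  }

  # Control wells fill the outermost columns top-down (left edge, right edge,
  # then inward), in the order negative, background, positive.
  col_order <- integer(0)
  lo <- 1L; hi <- n_cols
  while (lo <= hi) {
    col_order <- c(col_order, lo, if (hi > lo) hi)
    lo <- lo + 1L; hi <- hi - 1L
  }
  ctrl_pos <- data.frame(
    row = rep(seq_len(n_rows), times = n_cols),
    col = rep(col_order, each = n_rows)
  )[seq_len(n_ctrl), , drop = FALSE]
  ctrl_pos$content <- rep(c("negative_control", "background",
                            "positive_control"), c(n_neg, n_bg, n_pos))

  all_pos <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  all_pos <- all_pos[order(all_pos$row, all_pos$col), c("row", "col")]
  is_ctrl <- paste(all_pos$row, all_pos$col) %in%
    paste(ctrl_pos$row, ctrl_pos$col)
  sample_pos <- all_pos[!is_ctrl, , drop = FALSE]

  set.seed(well_seed(seed, "layout"))
  gene_order <- sample(library$genes$gene_id)

  plates <- list()
  for (idx in sort(unique(library$sirnas$index))) {
    sirnas_i <- library$sirnas[library$sirnas$index == idx, ]
    sirnas_i <- sirnas_i[match(gene_order, sirnas_i$gene_id), ]
    sirnas_i <- sirnas_i[!is.na(sirnas_i$sirna_id), ]
    n_plates <- ceiling(nrow(sirnas_i) / samples_per_plate)
    for (p in seq_len(n_plates)) {
      plate_id <- sprintf("P%02d-%02d", idx, p)
      chunk <- sirnas_i[((p - 1) * samples_per_plate + 1):
                          min(p * samples_per_plate, nrow(sirnas_i)), ]
      n_chunk <- nrow(chunk)
      n_spare <- nrow(sample_pos) - n_chunk  # unfilled sample positions
      wells <- tibble(
        plate_id = plate_id,
        plate_set = idx,
        row = c(ctrl_pos$row, sample_pos$row),
        col = c(ctrl_pos$col, sample_pos$col),
        content = c(ctrl_pos$content,
                    rep(c("sample", "empty"), c(n_chunk, n_spare))),
        sirna_id = c(rep(NA_character_, n_ctrl), chunk$sirna_id,
                     rep(NA_character_, n_spare)),
        gene_id = c(rep(NA_character_, n_ctrl), chunk$gene_id,
                    rep(NA_character_, n_spare))
      )
      plates[[plate_id]] <- wells
    }
  }
  layout <- bind_rows(plates)
  layout$well_id <- well_name(layout$row, layout$col)
  layout <- layout[order(layout$plate_id, layout$row, layout$col),
                   c("plate_id", "plate_set", "well_id", "row", "col",
                     "content", "sirna_id", "gene_id")]
  class(layout) <- c("plate_layout", class(layout))
  layout
}
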