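#' Flag a single siRNA by its robust z-score
#'
#' An siRNA is a hit when its robust z-score reaches the threshold in either
#' direction; both boundaries are inclusive (z >= threshold or
#' z <= -threshold).
#'
#' @param z Numeric vector of robust z-scores (finite).
#' @param threshold Positive hit threshold (default 2).
#' @return Integer vector: `+1` (up hit), `-1` (down hit) or `0`.
#' @export
#' @examples
#' flag_sirna(c(2, 1.999, -2))  # 1 0 -1
flag_sirna <- function(z, threshold = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_hcs("`threshold` must be a single positive number.",
             "parameter_error")
  }
  if (any(!is.finite(z))) {
    stop_hcs("z-scores must be finite.", "parameter_error")
  }
  as.integer(sign(z) * (abs(z) >= threshold))
}

#' Score one gene from its siRNA z-scores
#'
#' A gene is called a candidate when at least `min_pass` of its siRNAs pass
#' the threshold *in the same direction*. Requiring concordant direction is
#' an interpretation choice: a gene whose siRNAs score +2.2 and -2.2 is
#' biologically incoherent, so opposite-sign passes do not add up. The
#' gene's direction is its majority passing sign; cumulative and mean
#' z-scores summarize its overall effect.
#'
#' @param gene_id Gene identifier.
#' @param z_values Numeric vector of per-siRNA robust z-scores (>= 1 value),
#'   ordered by siRNA index.
#' @param threshold Per-siRNA hit threshold (default 2).
#' @param min_pass Minimum number of same-direction passing siRNAs for a
#'   candidate call (default 2).
#' @param n_expected Expected number of siRNAs per gene (default
#'   `length(z_values)`); genes with fewer observed values are flagged
#'   `incomplete`.
#' @return One-row tibble: `gene_id`, `n_sirnas`, `mean_z`, `cum_z`,
#'   `n_pass_pos`, `n_pass_neg`, `candidate`, `direction` (`"up"`, `"down"`
#'   or `"none"`), `incomplete`.
#' @export
#' @examples
#' score_gene("MDM2", c(2.5, 2.1, 0.4))
score_gene <- function(gene_id, z_values, threshold = 2, min_pass = 2,
                       n_expected = length(z_values)) {
  if (length(z_values) == 0) {
    stop_hcs("A gene needs at least one z-score to be scored.",
             "parameter_error")
  }
  flags <- flag_sirna(z_values, threshold)
  n_pos <- sum(flags == 1L)
  n_neg <- sum(flags == -1L)
  candidate <- max(n_pos, n_neg) >= min_pass
  direction <- "none"
  if (candidate) {
    if (n_pos > n_neg) {
      direction <- "up"
    } else if (n_neg > n_pos) {
      direction <- "down"
    } else {
      # equal opposing passes: incoherent, not a candidate
      candidate <- FALSE
    }
  }
  cum_z <- sum(z_values)
  n_z <- length(z_values)
  tibble(gene_id = gene_id, n_sirnas = n_z, z_values = list(z_values),
         mean_z = cum_z / n_z, cum_z = cum_z,
         n_pass_pos = n_pos, n_pass_neg = n_neg,
         candidate = candidate, direction = direction,
         incomplete = n_z < n_expected)
}

#' Gene-level scores from a table of siRNA z-scores
#'
#' Groups sample-well z-score records by gene and applies [score_gene()].
#' Only contributing sample wells enter; genes with fewer valid z-scores
#' than `sirnas_per_gene` (dropped wells) are scored on the available values
#' and flagged `incomplete`.
#'
#' @param zrecords Z-score tibble from [robust_zscore()] with `gene_id`,
#'   `sirna_id`, `z` (and optionally `content`, `contributing`,
#'   `gene_class`).
#' @param threshold,min_pass Hit-calling parameters (defaults 2 and 2).
#' @param sirnas_per_gene Designed siRNAs per gene (default 3).
#' @return A `GeneScore` tibble, one row per gene, with per-siRNA z-scores
#'   in the list column `z_values` (ordered by siRNA identifier, i.e. by
#'   siRNA index).
#' @export
score_genes <- function(zrecords, threshold = 2, min_pass = 2,
                        sirnas_per_gene = 3) {
  recs <- zrecords
  if ("content" %in% names(recs)) recs <- recs[recs$content == "sample", ]
  if ("contributing" %in% names(recs)) recs <- recs[recs$contributing, ]
  recs <- recs[!is.na(recs$gene_id) & !is.na(recs$z), ]
  if (nrow(recs) == 0) {
    stop_hcs("No scoreable sample wells in the z-score table.", "data_error")
  }
  recs <- recs[order(recs$gene_id, recs$sirna_id), ]
  classes <- if ("gene_class" %in% names(recs)) {
    recs |> distinct(.data$gene_id, .data$gene_class)
  } else {
    NULL
  }
  scores <- recs |>
    group_by(.data$gene_id) |>
    group_modify(function(d, key) {
      s <- score_gene(key$gene_id, d$z, threshold = threshold,
                      min_pass = min_pass, n_expected = sirnas_per_gene)
      s[, setdiff(names(s), "gene_id")]
    }) |>
    ungroup()
  if (!is.null(classes)) {
    scores <- left_join(scores, classes, by = "gene_id") |>
      relocate(.data$gene_class, .after = "gene_id")
  }
  scores
}

#' Rank gene scores into a hit table
#'
#' Orders genes by cumulative z-score — by absolute value for the combined
#' list (default), or signed for separate increase/decrease lists — with a
#' stable sort and lexicographic gene-id tie-breaking. Candidates are listed
#' before non-candidates when `candidates_first` is set.
#'
#' @param scores `GeneScore` tibble from [score_genes()].
#' @param order `"abs_cum_z_desc"` (default), `"cum_z_desc"` or
#'   `"cum_z_asc"`.
#' @param candidates_first List candidate genes before non-candidates
#'   (default `TRUE`).
#' @return The scores with a `rank` column (1..n in list order), reordered.
#' @export
rank_candidates <- function(scores,
                            order = c("abs_cum_z_desc", "cum_z_desc",
                                      "cum_z_asc"),
                            candidates_first = TRUE) {
  order <- match.arg(order)
  if (nrow(scores) == 0) {
    stop_hcs("Cannot rank an empty score table.", "parameter_error")
  }
  key <- switch(order,
                abs_cum_z_desc = -abs(scores$cum_z),
                cum_z_desc = -scores$cum_z,
                cum_z_asc = scores$cum_z)
  first <- if (candidates_first) !scores$candidate else rep(FALSE, nrow(scores))
  idx <- order(first, key, scores$gene_id, method = "radix")
  out <- scores[idx, ]
  out$rank <- seq_len(nrow(out))
  out
}
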