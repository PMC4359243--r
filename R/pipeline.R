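#' Screen run configuration
#'
#' Nested configuration with defaults matching the screen design: a library
#' of 327 ubiquitin-ligase and 92 DUB genes with 3 siRNAs per gene, 96-well
#' plates (80 samples + 16 control/background wells), a per-siRNA hit
#' threshold of |z| >= 2 and at least 2 concordant siRNAs per candidate
#' gene. Overrides may be passed as named sections or as a single nested
#' list (e.g. from [read_run_config()]); unrecognized sections are an error.
#'
#' @param ... Named top-level sections to override (`library`, `layout`,
#'   `model`, `treated`, `mode`, `image`, `segmentation`, `min_nuclei`,
#'   `normalize`, `hits`), or one unnamed nested list of such sections.
#' @return A complete configuration list.
#' @export
#' @examples
#' cfg <- screen_config(library = list(n_ligases = 10, n_dubs = 2))
#' cfg$hits$threshold
screen_config <- function(...) {
  defaults <- list(
    library = list(
      n_ligases = 327, n_dubs = 92, sirnas_per_gene = 3,
      effect_config = list(fraction_down = 0.05, fraction_up = 0.05,
                           delta_magnitude = log(2)),
      efficacy_range = c(0.6, 0.95)),
    layout = list(
      plate_format = c(8, 12), samples_per_plate = 80,
      controls = list(n_negative = 4, n_positive = 8, n_background = 4)),
    model = model_params(),
    treated = TRUE,
    mode = "wells",
    image = image_params(),
    segmentation = list(threshold_method = "otsu", threshold = NULL,
                        min_area = 40, max_area = 5000, connectivity = 8,
                        exclude_border = TRUE),
    min_nuclei = 50,
    normalize = list(include_controls = FALSE, mad_scaled = FALSE,
                     scope = "per_plate", min_wells = 8),
    hits = list(threshold = 2, min_pass = 2)
  )
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots))) dots <- dots[[1]]
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(defaults))
    if (length(unknown) > 0 || is.null(names(dots)) ||
        any(names(dots) == "")) {
      stop_hcs(paste0("Unknown configuration section(s): ",
                      paste(unknown, collapse = ", ")), "config_error")
    }
    defaults <- modifyList(defaults, dots)
  }
  if (!defaults$mode %in% c("wells", "images")) {
    stop_hcs("`mode` must be 'wells' or 'images'.", "config_error")
  }
  defaults
}

#' Quantify a directory of rendered plate images
#'
#' Reads the `{plate}_{well}_{channel}.tif` pair for every non-empty well in
#' the layout, segments nuclei, and aggregates to well measurements.
#'
#' @param dir Directory holding the TIFF pairs.
#' @param layout `plate_layout` of the imaged wells.
#' @param params Segmentation parameters from [segment_params()].
#' @param min_nuclei Minimum nucleus count for a valid well.
#' @return Well-measurement tibble: `plate_id`, `well_id`, `sirna_id`,
#'   `n_nuclei`, `raw_value`, `valid`.
#' @export
quantify_plate <- function(dir, layout, params = segment_params(),
                           min_nuclei = 50) {
  active <- layout[layout$content != "empty", ]
  rows <- vector("list", nrow(active))
  for (i in seq_len(nrow(active))) {
    w <- active[i, ]
    pair <- read_image_pair(dir, w$plate_id, w$well_id)
    m <- quantify_well(pair, params = params, min_nuclei = min_nuclei)
    m$sirna_id <- w$sirna_id
    rows[[i]] <- m
  }
  bind_rows(rows)[, c("plate_id", "well_id", "sirna_id", "n_nuclei",
                      "raw_value", "valid")]
}

#' Analyse well measurements into a ranked hit table
#'
#' The analysis half of the pipeline: background subtraction, per-plate
#' robust z-scoring, gene-level scoring and ranking.
#'
#' @param wells Well-measurement tibble (`plate_id`, `well_id`, `sirna_id`,
#'   `n_nuclei`, `raw_value`, `valid`).
#' @param layout `plate_layout` supplying well content and gene identity.
#' @param config Configuration from [screen_config()].
#' @param genes Optional gene table carrying `gene_id`, `gene_class`.
#' @return List: `wells` (with corrected values), `zscores`, `gene_scores`,
#'   `hit_table`, `report` (character lines).
#' @export
analyze_wells <- function(wells, layout, config = screen_config(),
                          genes = NULL) {
  corrected <- subtract_background(wells, layout,
                                   scope = config$normalize$scope)
  zrec <- robust_zscore(corrected, value_col = "corrected_value",
                        include_controls = config$normalize$include_controls,
                        mad_scaled = config$normalize$mad_scaled,
                        min_wells = config$normalize$min_wells)
  if (!is.null(genes)) {
    zrec <- left_join(zrec, genes[, c("gene_id", "gene_class")],
                      by = "gene_id")
  }
  scores <- score_genes(zrec, threshold = config$hits$threshold,
                        min_pass = config$hits$min_pass,
                        sirnas_per_gene = config$library$sirnas_per_gene)
  hits <- rank_candidates(scores, order = "abs_cum_z_desc")
  list(wells = corrected, zscores = zrec, gene_scores = scores,
       hit_table = hits,
       report = screen_report(hits, zrec, corrected, config))
}

screen_report <- function(hits, zrec, wells, config, top_n = 20) {
  n_plates <- length(unique(wells$plate_id))
  n_sample <- sum(wells$content == "sample")
  n_dropped <- sum(wells$content == "sample" & !wells$valid)
  cand <- hits[hits$candidate, ]
  top <- head(cand, top_n)
  lines <- c(
    "High-content siRNA screen report",
    "================================",
    sprintf("Plates analysed: %d; sample wells: %d (%d dropped, < %d nuclei)",
            n_plates, n_sample, n_dropped, config$min_nuclei),
    sprintf("Hit threshold: |z| >= %g; candidate rule: >= %d concordant siRNAs",
            config$hits$threshold, config$hits$min_pass),
    sprintf("Candidate genes: %d (%d up, %d down) of %d scored",
            nrow(cand), sum(cand$direction == "up"),
            sum(cand$direction == "down"), nrow(hits)),
    "",
    sprintf("Top %d candidates by |cumulative z|:", nrow(top)),
    sprintf("%-10s %-8s %9s %9s %6s", "gene", "dir", "cum_z", "mean_z",
            "pass"))
  for (i in seq_len(nrow(top))) {
    g <- top[i, ]
    lines <- c(lines, sprintf(
      "%-10s %-8s %9.2f %9.2f %3d/%d", g$gene_id, g$direction, g$cum_z,
      g$mean_z, max(g$n_pass_pos, g$n_pass_neg), g$n_sirnas))
  }
  lines
}

#' Run the full screen pipeline on a simulated dataset
#'
#' Simulates a screen (well-level or image mode), quantifies it, and runs
#' background subtraction, robust z-scoring, hit calling and reporting.
#' When `output_dir` is given, writes the plate map, well table, z-score
#' table, hit table, mean-z-per-gene table, plain-text report and a run
#' manifest.
#'
#' @param config Configuration from [screen_config()].
#' @param seed Integer seed driving every random draw.
#' @param output_dir Optional output directory.
#' @return List: everything from [analyze_wells()] plus `sim` (the
#'   simulated screen, including its truth table) and `output_files`.
#' @export
run_screen <- function(config = screen_config(), seed = 1,
                       output_dir = NULL) {
  img_dir <- if (identical(config$mode, "images")) {
    file.path(output_dir %||% tempdir(), "images")
  }
  sim <- simulate_screen(config, seed = seed, output_dir = img_dir)
  wells <- if (identical(config$mode, "images")) {
    quantify_plate(img_dir, sim$layout,
                   params = do.call(segment_params, config$segmentation),
                   min_nuclei = config$min_nuclei)
  } else {
    sim$wells
  }
  res <- analyze_wells(wells, sim$layout, config, genes = sim$library$genes)
  res$sim <- sim
  res$output_files <- character()

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      plate_map = file.path(output_dir, "plate_map.csv"),
      wells = file.path(output_dir, "well_table.tsv"),
      zscores = file.path(output_dir, "zscore_table.tsv"),
      hits = file.path(output_dir, "hit_table.tsv"),
      mean_z = file.path(output_dir, "gene_mean_z.tsv"),
      truth = file.path(output_dir, "truth_genes.tsv"),
      report = file.path(output_dir, "report.txt"))
    write_plate_map(sim$layout, paths[["plate_map"]])
    write_well_table(res$wells, paths[["wells"]])
    write_zscore_table(res$zscores, paths[["zscores"]])
    write_hit_table(res$hit_table, paths[["hits"]],
                    sirnas_per_gene = config$library$sirnas_per_gene)
    mean_z <- res$hit_table[, c("gene_id", "gene_class", "mean_z", "cum_z",
                                "candidate", "direction")]
    write_delim_atomic(as.data.frame(mean_z), paths[["mean_z"]], "\t")
    write_delim_atomic(as.data.frame(sim$truth$genes), paths[["truth"]],
                       "\t")
    write_atomic(function(tmp) {
      writeLines(res$report, tmp)
    }, paths[["report"]])
    manifest_path <- file.path(output_dir, "manifest.json")
    write_manifest(manifest_path, config, seed, unname(paths))
    res$output_files <- c(paths, manifest = manifest_path)
  }
  res
}

#' Score hit recovery against the generator's ground truth
#'
#' Compares a ranked hit table with the truth table's implanted effects.
#' A true positive is an implanted gene called candidate with the direction
#' matching the sign of its implanted effect; a true negative is a null
#' gene not called.
#'
#' @param hit_table Ranked `GeneScore` tibble.
#' @param truth_genes Gene truth tibble with `gene_id`, `effect_delta`.
#' @return One-row tibble: `n_implanted`, `n_null`, `tp`, `tn`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_recovery <- function(hit_table, truth_genes) {
  m <- left_join(truth_genes[, c("gene_id", "effect_delta")],
                 hit_table[, c("gene_id", "candidate", "direction")],
                 by = "gene_id")
  m$candidate[is.na(m$candidate)] <- FALSE
  implanted <- m$effect_delta != 0
  truth_dir <- ifelse(m$effect_delta > 0, "up", "down")
  tp <- sum(implanted & m$candidate & m$direction == truth_dir, na.rm = TRUE)
  tn <- sum(!implanted & !m$candidate)
  tibble(n_implanted = sum(implanted), n_null = sum(!implanted),
         tp = tp, tn = tn,
         sensitivity = if (sum(implanted) > 0) tp / sum(implanted) else NA,
         specificity = if (sum(!implanted) > 0) tn / sum(!implanted) else NA)
}
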