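# Table readers/writers. All tables are single-header delimited UTF-8 with
# missing values as empty fields; writes go through a write-then-rename so
# an interrupted run never leaves a truncated file.

write_atomic <- function(write_fn, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)  # cross-device fallback
  }
  invisible(path)
}

write_delim_atomic <- function(df, path, delim) {
  write_atomic(function(tmp) {
    readr::write_delim(df, tmp, delim = delim, na = "")
  }, path)
}

read_checked <- function(path, delim, col_types, what) {
  if (!file.exists(path)) {
    stop_hcs(sprintf("%s file not found: %s", what, path), "parse_error")
  }
  df <- suppressWarnings(
    readr::read_delim(path, delim = delim, col_types = col_types,
                      na = c("", "NA"), show_col_types = FALSE,
                      progress = FALSE))
  missing <- setdiff(names(col_types$cols), names(df))
  if (length(missing) > 0) {
    stop_hcs(sprintf("%s file %s is missing column(s): %s", what, path,
                     paste(missing, collapse = ", ")), "parse_error")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop_hcs(sprintf(
      "%s file %s has %d malformed value(s); first at line %d, column %d (%s).",
      what, path, nrow(probs), probs$row[1], probs$col[1],
      probs$expected[1]), "parse_error")
  }
  df <- df[, names(col_types$cols)]
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

#' Read and write plate-map tables
#'
#' Plate maps are comma-separated with columns `plate_id`, `well_id`, `row`,
#' `col`, `content`, `sirna_id`, `gene_id` (empty fields for control wells'
#' siRNA/gene).
#'
#' @param layout A `plate_layout` tibble (the `plate_set` column, derivable
#'   from `plate_id`, is not serialized).
#' @param path File path.
#' @return `read_plate_map()` returns a `plate_layout` tibble;
#'   `write_plate_map()` returns the path invisibly.
#' @export
write_plate_map <- function(layout, path) {
  cols <- c("plate_id", "well_id", "row", "col", "content", "sirna_id",
            "gene_id")
  write_delim_atomic(as.data.frame(layout)[, cols], path, ",")
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  ct <- readr::cols(plate_id = "c", well_id = "c", row = "i", col = "i",
                    content = "c", sirna_id = "c", gene_id = "c")
  df <- read_checked(path, ",", ct, "Plate map")
  bad <- !df$content %in% c("sample", "negative_control", "positive_control",
                            "background", "empty")
  if (any(bad)) {
    stop_hcs(sprintf("Plate map %s: unknown well content '%s' at line %d.",
                     path, df$content[which(bad)[1]], which(bad)[1] + 1L),
             "parse_error")
  }
  df$plate_set <- as.integer(sub("^P(\\d+)-.*$", "\\1", df$plate_id))
  df <- df[, c("plate_id", "plate_set", "well_id", "row", "col", "content",
               "sirna_id", "gene_id")]
  class(df) <- c("plate_layout", class(df))
  df
}

#' Read and write well-measurement tables
#'
#' Tab-separated, one row per well: `plate_id`, `well_id`, `sirna_id`,
#' `n_nuclei`, `raw_value`, `corrected_value`, `valid`.
#'
#' @param wells Well-measurement tibble.
#' @param path File path.
#' @return `read_well_table()` returns a tibble; the writer returns the
#'   path invisibly.
#' @export
write_well_table <- function(wells, path) {
  cols <- c("plate_id", "well_id", "sirna_id", "n_nuclei", "raw_value",
            "corrected_value", "valid")
  df <- as.data.frame(wells)
  for (c_ in setdiff(cols, names(df))) df[[c_]] <- NA
  write_delim_atomic(df[, cols], path, "\t")
}

#' @rdname write_well_table
#' @export
read_well_table <- function(path) {
  ct <- readr::cols(plate_id = "c", well_id = "c", sirna_id = "c",
                    n_nuclei = "i", raw_value = "d", corrected_value = "d",
                    valid = "l")
  read_checked(path, "\t", ct, "Well table")
}

#' Read and write z-score tables
#'
#' Tab-separated records of the per-plate normalization: the well columns
#' plus `gene_id`, `value` (the normalized quantity), `z`, `plate_median`,
#' `plate_mad` and the `contributing` flag.
#'
#' @param zrecords Z-score tibble from [robust_zscore()].
#' @param path File path.
#' @return `read_zscore_table()` returns a tibble; the writer returns the
#'   path invisibly.
#' @export
write_zscore_table <- function(zrecords, path) {
  cols <- c("plate_id", "well_id", "sirna_id", "gene_id", "content", "value",
            "z", "plate_median", "plate_mad", "contributing")
  df <- as.data.frame(zrecords)
  for (c_ in setdiff(cols, names(df))) df[[c_]] <- NA
  write_delim_atomic(df[, cols], path, "\t")
}

#' @rdname write_zscore_table
#' @export
read_zscore_table <- function(path) {
  ct <- readr::cols(plate_id = "c", well_id = "c", sirna_id = "c",
                    gene_id = "c", content = "c", value = "d", z = "d",
                    plate_median = "d", plate_mad = "d", contributing = "l")
  read_checked(path, "\t", ct, "Z-score table")
}

#' Read and write gene-level hit tables
#'
#' Tab-separated, one row per gene: `gene_id`, `gene_class`, per-siRNA
#' z-scores `z1..zK`, `mean_z`, `cum_z`, pass counts, `candidate`,
#' `direction`, `rank`, `incomplete`.
#'
#' @param hits Ranked `GeneScore` tibble from [rank_candidates()].
#' @param path File path.
#' @param sirnas_per_gene Number of per-siRNA z-score columns to serialize
#'   (default 3).
#' @return `read_hit_table()` returns a tibble; the writer returns the path
#'   invisibly.
#' @export
write_hit_table <- function(hits, path, sirnas_per_gene = 3) {
  df <- as.data.frame(hits[, setdiff(names(hits), "z_values")])
  if ("z_values" %in% names(hits)) {
    for (k in seq_len(sirnas_per_gene)) {
      df[[paste0("z", k)]] <- vapply(hits$z_values, function(z) {
        if (length(z) >= k) z[k] else NA_real_
      }, numeric(1))
    }
  }
  if (!"gene_class" %in% names(df)) df$gene_class <- NA_character_
  cols <- c("gene_id", "gene_class", paste0("z", seq_len(sirnas_per_gene)),
            "mean_z", "cum_z", "n_pass_pos", "n_pass_neg", "candidate",
            "direction", "rank", "incomplete")
  cols <- intersect(cols, names(df))
  write_delim_atomic(df[, cols], path, "\t")
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path, sirnas_per_gene = 3) {
  zcols <- setNames(rep("d", sirnas_per_gene),
                    paste0("z", seq_len(sirnas_per_gene)))
  ct <- do.call(readr::cols, c(
    list(gene_id = "c", gene_class = "c"), as.list(zcols),
    list(mean_z = "d", cum_z = "d", n_pass_pos = "i", n_pass_neg = "i",
         candidate = "l", direction = "c", rank = "i", incomplete = "l")))
  read_checked(path, "\t", ct, "Hit table")
}

#' Read a qPCR Ct table
#'
#' Comma-separated long format: `sample_id`, `gene`, `ct` (one row per
#' technical replicate).
#'
#' @param path File path.
#' @return Tibble with columns `sample_id`, `gene`, `ct`.
#' @export
read_qpcr <- function(path) {
  ct <- readr::cols(sample_id = "c", gene = "c", ct = "d")
  read_checked(path, ",", ct, "qPCR")
}

#' Write and read two-channel well images as 16-bit TIFF
#'
#' One single-channel file per channel, named
#' `{plate}_{well}_{channel}.tif`. Pixel values are rounded to integers in
#' `[0, 65535]`; within that range the round trip is pixel-identical.
#'
#' @param pair An `image_pair` from [render_images()].
#' @param dir Output directory (created if missing).
#' @param plate_id,well_id Well identity used in the file names.
#' @return `write_image_pair()` returns a one-row tibble with `plate_id`,
#'   `well_id`, `hoechst_path`, `signal_path`; `read_image_pair()` returns
#'   an `image_pair`.
#' @export
write_image_pair <- function(pair, dir, plate_id = pair$plate_id,
                             well_id = pair$well_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(img, channel) {
    if (max(img) > 65535) {
      stop_hcs("Pixel values exceed the 16-bit range.", "data_error")
    }
    path <- file.path(dir, sprintf("%s_%s_%s.tif", plate_id, well_id,
                                   channel))
    write_atomic(function(tmp) {
      tiff::writeTIFF(round(img) / 65535, tmp, bits.per.sample = 16)
    }, path)
    path
  }
  tibble(plate_id = plate_id, well_id = well_id,
         hoechst_path = write_one(pair$hoechst, "hoechst"),
         signal_path = write_one(pair$signal, "signal"))
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(dir, plate_id, well_id) {
  read_one <- function(channel) {
    path <- file.path(dir, sprintf("%s_%s_%s.tif", plate_id, well_id,
                                   channel))
    if (!file.exists(path)) {
      stop_hcs(sprintf("Image file not found: %s", path), "parse_error")
    }
    round(tiff::readTIFF(path) * 65535)
  }
  structure(list(hoechst = read_one("hoechst"), signal = read_one("signal"),
                 plate_id = plate_id, well_id = well_id),
            class = "image_pair")
}

#' Read and write run configurations
#'
#' Configurations are stored as YAML (nested key-value sections) and
#' validated/completed against the package defaults from [screen_config()].
#'
#' @param config A configuration list.
#' @param path File path.
#' @return `read_run_config()` returns a complete configuration list.
#' @export
write_run_config <- function(config, path) {
  write_atomic(function(tmp) yaml::write_yaml(config, tmp), path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_hcs(sprintf("Config file not found: %s", path), "config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_hcs(sprintf("Config file %s is not valid YAML: %s", path,
                     conditionMessage(e)), "config_error")
  })
  do.call(screen_config, list(raw))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-identically: the
#' configuration snapshot, the seed, MD5 digests of the output files, the
#' package version and a timestamp.
#'
#' @param path Manifest path (JSON).
#' @param config Configuration list used for the run.
#' @param seed Seed used for the run.
#' @param files Character vector of output file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character()) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "hcscreen",
    version = as.character(packageVersion("hcscreen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = lapply(setNames(files, basename(files)),
                   function(f) list(path = f,
                                    md5 = unname(tools::md5sum(f))))
  )
  write_atomic(function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }, path)
  invisible(manifest)
}
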