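#' Generative-model parameters for the synthetic screen
#'
#' Per-cell signal intensity follows a log-normal model: for a sample well,
#' `log(signal) = mu0 + tau * treated + efficacy * effect_delta * treated +
#' plate_effect + well_noise + cell_noise`. Fluorescence intensities are
#' positive and right-skewed, and knockdown/treatment effects act
#' multiplicatively, hence additive effects on the log scale.
#'
#' @param mu0 Baseline mean per-cell log-intensity (default `log(100)`,
#'   arbitrary fluorescence units).
#' @param tau Treatment effect on log-intensity (default `log(3)`: genotoxic
#'   treatment raises the damage signal about three-fold).
#' @param sigma_cell Cell-to-cell SD of log-intensity (default 0.5).
#' @param sigma_well Well-to-well SD of log-intensity (default 0.1).
#' @param sigma_plate SD of per-plate log-scale effects (default 0.15);
#'   plate effects are what the per-plate robust z-score removes.
#' @param lambda_cells Poisson mean cell count per well (default 500).
#' @param background_level Median per-cell signal in background
#'   (no-primary-antibody) wells (default 5).
#' @param sigma_background SD of log-signal in background wells (default 0.2).
#' @param positive_delta Implanted effect of positive-control wells
#'   (default `log(3)`, a strong increase).
#' @param hoechst_level,sigma_hoechst Median and log-SD of the nuclear-stain
#'   channel (defaults 500 and 0.2); independent of the signal channel.
#'
#' @return A named list of model parameters.
#' @export
model_params <- function(mu0 = log(100), tau = log(3), sigma_cell = 0.5,
                         sigma_well = 0.1, sigma_plate = 0.15,
                         lambda_cells = 500, background_level = 5,
                         sigma_background = 0.2, positive_delta = log(3),
                         hoechst_level = 500, sigma_hoechst = 0.2) {
  list(mu0 = mu0, tau = tau, sigma_cell = sigma_cell, sigma_well = sigma_well,
       sigma_plate = sigma_plate, lambda_cells = lambda_cells,
       background_level = background_level,
       sigma_background = sigma_background, positive_delta = positive_delta,
       hoechst_level = hoechst_level, sigma_hoechst = sigma_hoechst)
}

#' Ground-truth table for a synthetic screen
#'
#' Records everything the generator implanted so that downstream recovery can
#' be scored against it: the per-gene effects, per-siRNA efficacies, per-plate
#' effects, the expected mean signal of every non-empty well, and the model
#' parameters and seed.
#'
#' The expected well mean integrates the log-normal cell and well noise:
#' `E[signal] = exp(mu_well + (sigma_well^2 + sigma_cell^2) / 2)` where
#' `mu_well` is the well's deterministic log-level (including its plate
#' effect).
#'
#' @param library A `sirna_library`.
#' @param layout A `plate_layout` from [layout_plates()].
#' @param params Model parameters from [model_params()].
#' @param treated Is the screen run under treatment? (Default `TRUE`; the
#'   screen readout is treatment-induced damage.)
#' @param seed Integer seed; plate effects and all downstream per-well draws
#'   are keyed to it.
#'
#' @return An object of class `screen_truth`: list with tibbles `genes`,
#'   `sirnas`, `plates` (`plate_id`, `plate_effect`), `wells` (per-well
#'   expected means), plus `params`, `treated`, `seed`.
#' @export
build_truth <- function(library, layout, params = model_params(),
                        treated = TRUE, seed = 1) {
  stopifnot(inherits(library, "sirna_library"))
  plate_ids <- unique(layout$plate_id)
  plate_effect <- vapply(plate_ids, function(p) {
    set.seed(well_seed(seed, p, "plate"))
    rnorm(1, 0, params$sigma_plate)
  }, numeric(1))
  plates <- tibble(plate_id = plate_ids, plate_effect = unname(plate_effect))

  wells <- layout[layout$content != "empty", ]
  wells <- left_join(wells, plates, by = "plate_id")
  wells <- left_join(wells, library$sirnas[, c("sirna_id", "efficacy")],
                     by = "sirna_id")
  wells <- left_join(wells, library$genes[, c("gene_id", "effect_delta")],
                     by = "gene_id")
  wells$efficacy[wells$content == "positive_control"] <- 1
  wells$effect_delta[wells$content == "positive_control"] <-
    params$positive_delta
  wells$efficacy[wells$content == "negative_control"] <- 1
  wells$effect_delta[wells$content == "negative_control"] <- 0

  t_num <- as.numeric(treated)
  mu_well <- with(wells, params$mu0 + params$tau * t_num +
                    efficacy * effect_delta * t_num + plate_effect)
  noise_var <- params$sigma_well^2 + params$sigma_cell^2
  wells$expected_mean <- exp(mu_well + noise_var / 2)
  bg <- wells$content == "background"
  wells$expected_mean[bg] <-
    params$background_level * exp(params$sigma_background^2 / 2)

  structure(list(genes = library$genes, sirnas = library$sirnas,
                 plates = plates,
                 wells = as_tibble(wells[, c("plate_id", "well_id", "content",
                                             "sirna_id", "gene_id", "efficacy",
                                             "effect_delta", "plate_effect",
                                             "expected_mean")]),
                 params = params, treated = treated, seed = seed),
            class = "screen_truth")
}

# Deterministic per-well log-level and noise SD for a well spec resolved
# against the truth table; shared by cell- and measurement-level simulation.
well_model <- function(well, truth) {
  p <- truth$params
  tr <- truth$wells[truth$wells$plate_id == well$plate_id &
                      truth$wells$well_id == well$well_id, ]
  if (nrow(tr) != 1L) {
    stop_hcs(sprintf("Well %s/%s is not covered by the truth table.",
                     well$plate_id, well$well_id), "data_error")
  }
  if (tr$content == "background") {
    list(mu = log(p$background_level), sigma = p$sigma_background,
         sigma_well = 0, content = tr$content)
  } else {
    t_num <- as.numeric(truth$treated)
    list(mu = p$mu0 + p$tau * t_num +
           tr$efficacy * tr$effect_delta * t_num + tr$plate_effect,
         sigma = p$sigma_cell, sigma_well = p$sigma_well,
         content = tr$content)
  }
}

#' Simulate the cell population of one well
#'
#' Draws a Poisson cell count and log-normal per-cell signal intensities
#' according to the generative model recorded in the truth table. Background
#' wells receive only background noise. The RNG substream is keyed by
#' `(seed, plate_id, well_id)` so that a well's population is reproducible
#' regardless of the order in which wells are simulated.
#'
#' @param well A one-row well spec (list or data frame row) with `plate_id`
#'   and `well_id` resolvable in `truth`.
#' @param truth A `screen_truth` from [build_truth()].
#' @param treated Deprecated in favour of the truth table's `treated` flag;
#'   if supplied, overrides it for this well.
#' @param seed Screen-level seed.
#' @param positions If `TRUE`, also draw nucleus centres and radii for image
#'   rendering (`image_params` supplies the field size). Positions are drawn
#'   after intensities, so the intensity draws are identical with and without
#'   positions.
#' @param image_params Field geometry from [image_params()]; needed only when
#'   `positions = TRUE`.
#'
#' @return A tibble with one row per cell: `center_x`, `center_y`, `radius`
#'   (pixels; `NA` when `positions = FALSE`), `hoechst_level`, `signal_level`.
#'   Attributes `plate_id` and `well_id` identify the well.
#' @export
simulate_well_cells <- function(well, truth, treated = NULL, seed = 1,
                                positions = FALSE, image_params = NULL) {
  p <- truth$params
  if (!is.null(treated)) {
    truth$treated <- treated
  }
  mod <- well_model(well, truth)
  set.seed(well_seed(seed, well$plate_id, well$well_id))
  n <- rpois(1, p$lambda_cells)
  well_noise <- if (mod$sigma_well > 0) rnorm(1, 0, mod$sigma_well) else 0
  signal <- exp(mod$mu + well_noise + rnorm(n, 0, mod$sigma))
  hoechst <- exp(rnorm(n, log(p$hoechst_level), p$sigma_hoechst))
  if (positions) {
    if (is.null(image_params)) image_params <- hcscreen::image_params()
    radius <- pmax(3, rnorm(n, image_params$radius_mean,
                            image_params$radius_sd))
    pos <- place_cells(n, radius, image_params$width, image_params$height)
    cx <- pos$x; cy <- pos$y
  } else {
    cx <- cy <- radius <- rep(NA_real_, n)
  }
  cells <- tibble(center_x = cx, center_y = cy, radius = radius,
                  hoechst_level = hoechst, signal_level = signal)
  attr(cells, "plate_id") <- well$plate_id
  attr(cells, "well_id") <- well$well_id
  cells
}

# Sequential placement with rejection: each centre keeps a clearance of
# 1.4 * (r_i + r_j) from previously placed cells when achievable within 40
# tries, otherwise overlap is accepted (dense wells). The margin keeps the
# whole disc plus its point-spread halo away from the field border, so
# border-exclusion during segmentation never clips generated nuclei.
place_cells <- function(n, radius, width, height) {
  x <- y <- numeric(n)
  if (n == 0) return(list(x = x, y = y))
  for (i in seq_len(n)) {
    m <- radius[i] + 6
    for (try in seq_len(40L)) {
      xi <- runif(1, m, width - 1 - m)
      yi <- runif(1, m, height - 1 - m)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      ok <- all(sqrt((x[j] - xi)^2 + (y[j] - yi)^2) >=
                  1.4 * (radius[j] + radius[i]))
      if (ok) break
    }
    x[i] <- xi; y[i] <- yi
  }
  list(x = x, y = y)
}

# Well-level fast path: the measurement that ideal quantification of the
# well's cells would produce (mean per-cell signal, cell count).
simulate_well_measurement <- function(well, truth, seed = 1,
                                      min_nuclei = 50) {
  cells <- simulate_well_cells(well, truth, seed = seed, positions = FALSE)
  n <- nrow(cells)
  tibble(plate_id = well$plate_id, well_id = well$well_id,
         sirna_id = well$sirna_id %||% NA_character_,
         n_nuclei = n,
         raw_value = if (n >= 1) mean(cells$signal_level) else NA_real_,
         valid = n >= min_nuclei)
}

#' Simulate a complete synthetic screen
#'
#' End-to-end driver: generates the library, lays out the plates, builds the
#' ground-truth table and simulates every non-empty well. In `"wells"` mode
#' (the default) it emits the per-well measurement table directly — the
#' measurement that ideal image quantification would produce — which is the
#' fast path for statistical testing. In `"images"` mode it renders and
#' writes two-channel 16-bit TIFF pairs for each well instead.
#'
#' @param config Screen configuration from [screen_config()].
#' @param seed Integer screen seed; every random draw is keyed to it.
#' @param output_dir Directory for TIFF output (images mode); created if
#'   missing. Ignored in wells mode.
#'
#' @return A list of class `sim_screen`: `library`, `layout`, `truth`,
#'   `config`, `seed`, and either `wells` (measurement tibble with
#'   `plate_id`, `well_id`, `sirna_id`, `n_nuclei`, `raw_value`, `valid`) or
#'   `image_files` (tibble of written TIFF paths).
#' @export
simulate_screen <- function(config = screen_config(), seed = 1,
                            output_dir = NULL) {
  lib <- generate_library(
    n_ligases = config$library$n_ligases,
    n_dubs = config$library$n_dubs,
    sirnas_per_gene = config$library$sirnas_per_gene,
    effect_config = config$library$effect_config,
    efficacy_range = config$library$efficacy_range,
    seed = seed)
  layout <- layout_plates(
    lib, plate_format = config$layout$plate_format,
    samples_per_plate = config$layout$samples_per_plate,
    controls = config$layout$controls, seed = seed)
  truth <- build_truth(lib, layout, params = config$model,
                       treated = config$treated, seed = seed)
  active <- layout[layout$content != "empty", ]
  out <- list(library = lib, layout = layout, truth = truth,
              config = config, seed = seed)

  if (identical(config$mode, "images")) {
    if (is.null(output_dir)) {
      stop_hcs("Images mode needs an `output_dir`.", "parameter_error")
    }
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vector("list", nrow(active))
    for (i in seq_len(nrow(active))) {
      w <- active[i, ]
      cells <- simulate_well_cells(w, truth, seed = seed, positions = TRUE,
                                   image_params = config$image)
      pair <- render_images(cells, image_params = config$image,
                            seed = well_seed(seed, w$plate_id, w$well_id,
                                             "render"))
      files[[i]] <- write_image_pair(pair, output_dir, w$plate_id, w$well_id)
    }
    out$image_files <- bind_rows(files)
  } else {
    rows <- vector("list", nrow(active))
    for (i in seq_len(nrow(active))) {
      rows[[i]] <- simulate_well_measurement(active[i, ], truth, seed = seed,
                                             min_nuclei = config$min_nuclei)
    }
    out$wells <- bind_rows(rows)
  }
  structure(out, class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  cat(sprintf("<sim_screen> %d plates, %d genes, seed %d, mode %s\n",
              length(unique(x$layout$plate_id)), nrow(x$library$genes),
              x$seed, x$config$mode))
  invisible(x)
}
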