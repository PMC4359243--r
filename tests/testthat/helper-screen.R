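# Shared fixtures: small screens built in code.

# A compact screen configuration: n_genes genes, one 4x6 plate set per siRNA
# index, quick to simulate at well level.
tiny_config <- function(n_genes = 12, sirnas_per_gene = 2,
                        lambda_cells = 100,
                        effect = list(fraction_down = 0, fraction_up = 0,
                                      delta_magnitude = log(2))) {
  screen_config(
    library = list(n_ligases = n_genes, n_dubs = 0,
                   sirnas_per_gene = sirnas_per_gene,
                   effect_config = effect),
    layout = list(plate_format = c(4, 6), samples_per_plate = 18,
                  controls = list(n_negative = 2, n_positive = 2,
                                  n_background = 2)),
    model = list(lambda_cells = lambda_cells),
    min_nuclei = 10)
}

# One-gene library + single-plate layout + truth, for well-level draws.
tiny_truth <- function(effect_delta = 0, params = model_params(),
                       seed = 11, sirnas_per_gene = 1) {
  lib <- generate_library(
    n_ligases = 1, n_dubs = 0, sirnas_per_gene = sirnas_per_gene,
    effect_config = list(fraction_down = if (effect_delta < 0) 1 else 0,
                         fraction_up = if (effect_delta > 0) 1 else 0,
                         delta_magnitude = abs(effect_delta)),
    seed = seed)
  layout <- layout_plates(lib, plate_format = c(2, 2), samples_per_plate = 1,
                          controls = list(n_negative = 1, n_positive = 1,
                                          n_background = 1), seed = seed)
  truth <- build_truth(lib, layout, params = params, seed = seed)
  list(library = lib, layout = layout, truth = truth,
       sample_well = layout[layout$content == "sample", ][1, ])
}

# A hand-placed cell population with guaranteed separation, for rendering
# and segmentation oracles.
grid_population <- function(levels, hoechst = 500, radius = 10,
                            plate_id = "P01-01", well_id = "B02") {
  n <- length(levels)
  centers <- expand.grid(x = c(50, 128, 206), y = c(50, 128, 206))[seq_len(n), ]
  pop <- tibble::tibble(center_x = centers$x, center_y = centers$y,
                        radius = radius, hoechst_level = hoechst,
                        signal_level = levels)
  attr(pop, "plate_id") <- plate_id
  attr(pop, "well_id") <- well_id
  pop
}

# Independent brute-force oracle for the plate statistics: sort-based
# median and an explicit deviation list, no calls into the package.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracle_mad <- function(x) {
  m <- oracle_median(x)
  devs <- numeric(length(x))
  for (i in seq_along(x)) devs[i] <- abs(x[i] - m)
  oracle_median(devs)
}
oracle_z <- function(x) (x - oracle_median(x)) / oracle_mad(x)
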