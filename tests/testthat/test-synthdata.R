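test_that("library generation matches the screen design and is deterministic", {
  lib <- generate_library(seed = 7)
  expect_equal(nrow(lib$genes), 419)   # 327 ligases + 92 DUBs
  expect_equal(nrow(lib$sirnas), 1257) # 3 siRNAs per gene
  expect_equal(sum(lib$genes$gene_class == "ligase"), 327)
  expect_equal(sum(lib$genes$gene_class == "dub"), 92)
  expect_false(anyDuplicated(lib$genes$gene_id) > 0)
  expect_false(anyDuplicated(paste(lib$sirnas$gene_id, lib$sirnas$index)) > 0)
  expect_true(all(lib$sirnas$gene_id %in% lib$genes$gene_id))
  expect_true(all(is.finite(lib$genes$effect_delta)))

  # same seed twice -> identical; different seed -> different efficacies
  expect_identical(lib, generate_library(seed = 7))
  expect_false(identical(lib$sirnas$efficacy,
                         generate_library(seed = 8)$sirnas$efficacy))
})

test_that("implanted effects follow the effect configuration", {
  lib <- generate_library(
    n_ligases = 80, n_dubs = 20,
    effect_config = list(fraction_down = 0.1, fraction_up = 0.1,
                         delta_magnitude = log(2)), seed = 3)
  expect_equal(sum(lib$genes$effect_delta == -log(2)), 10)
  expect_equal(sum(lib$genes$effect_delta == log(2)), 10)
  expect_equal(sum(lib$genes$effect_delta == 0), 80)
  expect_true(all(lib$sirnas$efficacy >= 0.6 & lib$sirnas$efficacy <= 0.95))

  one <- generate_library(n_ligases = 1, n_dubs = 0, sirnas_per_gene = 1,
                          effect_config = list(fraction_down = 0,
                                               fraction_up = 0,
                                               delta_magnitude = 0),
                          seed = 0)
  expect_equal(nrow(one$genes), 1)
  expect_equal(one$genes$effect_delta, 0)
})

test_that("invalid library parameters are rejected", {
  expect_error(generate_library(n_ligases = 0, n_dubs = 0),
               class = "hcs_parameter_error")
  expect_error(generate_library(sirnas_per_gene = 0),
               class = "hcs_parameter_error")
  expect_error(generate_library(
    effect_config = list(fraction_down = 0.7, fraction_up = 0.6,
                         delta_magnitude = 1)),
    class = "hcs_parameter_error")
})

test_that("plate layout arithmetic, controls, and siRNA placement", {
  lib <- generate_library(seed = 7)
  layout <- layout_plates(lib, seed = 7)

  # ceil(419 / 80) = 6 plates per siRNA-index set, 3 sets -> 18 plates
  expect_equal(length(unique(layout$plate_id[layout$plate_set == 1])), 6)
  expect_equal(length(unique(layout$plate_id)), 18)

  # every siRNA placed exactly once
  placed <- layout$sirna_id[layout$content == "sample"]
  expect_setequal(placed, lib$sirnas$sirna_id)
  expect_false(anyDuplicated(placed) > 0)

  # well ids unique per plate, within the 8x12 format
  expect_false(any(duplicated(layout[, c("plate_id", "well_id")])))
  expect_true(all(layout$row >= 1 & layout$row <= 8))
  expect_true(all(layout$col >= 1 & layout$col <= 12))

  # every plate carries its control and background wells
  per_plate <- table(layout$plate_id, layout$content)
  expect_true(all(per_plate[, "background"] == 4))
  expect_true(all(per_plate[, "negative_control"] == 4))
  expect_true(all(per_plate[, "positive_control"] == 8))

  # exhaustive index separation: siRNAs of index i only on plate set i
  joined <- merge(layout[layout$content == "sample", ],
                  lib$sirnas[, c("sirna_id", "index")], by = "sirna_id")
  expect_true(all(joined$plate_set == joined$index))
})

test_that("degenerate and overfull layouts", {
  one <- generate_library(n_ligases = 1, n_dubs = 0, sirnas_per_gene = 1)
  lay <- layout_plates(one, plate_format = c(2, 2), samples_per_plate = 1,
                       controls = list(n_negative = 1, n_positive = 1,
                                       n_background = 1))
  expect_equal(length(unique(lay$plate_id)), 1)
  expect_equal(sum(lay$content == "sample"), 1)

  expect_error(
    layout_plates(one, plate_format = c(2, 2), samples_per_plate = 4,
                  controls = list(n_negative = 1, n_positive = 1,
                                  n_background = 1)),
    class = "hcs_layout_error")
  expect_error(
    layout_plates(one, controls = list(n_negative = 1, n_positive = 1,
                                       n_background = 0)),
    class = "hcs_layout_error")
})

test_that("per-cell intensity model recovers its parameters (Monte Carlo)", {
  p <- model_params(sigma_plate = 0, lambda_cells = 500)
  fx <- tiny_truth(effect_delta = 0, params = p, seed = 21)
  w <- fx$sample_well

  mean_log <- function(truth, seeds) {
    vapply(seeds, function(s) {
      mean(log(simulate_well_cells(w, truth, seed = s)$signal_level))
    }, numeric(1))
  }
  treated <- mean_log(fx$truth, 1:200)
  untr_truth <- build_truth(fx$library, fx$layout, params = p,
                            treated = FALSE, seed = 21)
  untreated <- mean_log(untr_truth, 1:200)

  # per-well mean log-intensity ~ N(mu, sigma_well^2 + sigma_cell^2/n)
  se <- sqrt((p$sigma_well^2 + p$sigma_cell^2 / p$lambda_cells) / 200)
  expect_lt(abs(mean(treated) - (p$mu0 + p$tau)), 3 * se)
  expect_lt(abs(mean(untreated) - p$mu0), 3 * se)
  expect_lt(abs(mean(treated) - mean(untreated) - p$tau), 3 * sqrt(2) * se)

  # knockdown gene sits below the null treated mean by efficacy * |delta|
  kd <- tiny_truth(effect_delta = -log(2), params = p, seed = 22)
  eff <- kd$truth$wells$efficacy[kd$truth$wells$content == "sample"]
  kd_mean <- mean(vapply(1:200, function(s) {
    mean(log(simulate_well_cells(kd$sample_well, kd$truth,
                                 seed = s)$signal_level))
  }, numeric(1)))
  gap <- (p$mu0 + p$tau) - kd_mean
  expect_lt(abs(gap - eff * log(2)), 3 * sqrt(2) * se)
})

test_that("cell counts are Poisson and wells are seed-reproducible", {
  p <- model_params(lambda_cells = 30)
  fx <- tiny_truth(params = p, seed = 31)
  counts <- vapply(1:600, function(s) {
    nrow(simulate_well_cells(fx$sample_well, fx$truth, seed = s))
  }, numeric(1))

  # chi-square goodness of fit against Poisson(30), tails lumped to
  # expected counts >= 5
  brk <- qpois(c(0.02, 0.98), p$lambda_cells)
  bins <- cut(pmin(pmax(counts, brk[1]), brk[2]), breaks = c(-Inf, brk[1]:brk[2]))
  probs <- diff(c(0, ppois(brk[1]:(brk[2] - 1), p$lambda_cells), 1))
  gof <- suppressWarnings(chisq.test(tabulate(bins, nbins = length(probs)),
                                     p = probs))
  expect_gt(gof$p.value, 0.01)

  # determinism and the empty-well edge case
  a <- simulate_well_cells(fx$sample_well, fx$truth, seed = 5)
  b <- simulate_well_cells(fx$sample_well, fx$truth, seed = 5)
  expect_identical(a, b)
  empty <- tiny_truth(params = model_params(lambda_cells = 0), seed = 31)
  expect_equal(nrow(simulate_well_cells(empty$sample_well, empty$truth,
                                        seed = 1)), 0)
  expect_error(
    simulate_well_cells(list(plate_id = "nope", well_id = "A01"), fx$truth),
    class = "hcs_data_error")
})

test_that("simulated screens are complete, consistent, and reproducible", {
  cfg <- tiny_config(n_genes = 12, sirnas_per_gene = 2)
  sim <- simulate_screen(cfg, seed = 4)

  active <- sim$layout[sim$layout$content != "empty", ]
  expect_equal(nrow(sim$wells), nrow(active))
  expect_setequal(paste(sim$truth$wells$plate_id, sim$truth$wells$well_id),
                  paste(active$plate_id, active$well_id))
  expect_setequal(sim$truth$genes$gene_id, sim$library$genes$gene_id)

  sim2 <- simulate_screen(cfg, seed = 4)
  expect_identical(sim$wells, sim2$wells)
  expect_false(identical(sim$wells$raw_value,
                         simulate_screen(cfg, seed = 5)$wells$raw_value))
})
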