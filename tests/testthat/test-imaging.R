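test_that("blank and degenerate images segment to zero nuclei", {
  blank <- matrix(7, 64, 64)
  masks <- segment_nuclei(blank)
  expect_equal(nrow(masks$features), 0)
  expect_true(all(masks$labels == 0))

  expect_error(segment_nuclei(matrix(1, 4, 4)), class = "hcs_parameter_error")
  expect_error(segment_nuclei(matrix(c(-1, rep(1, 255)), 16, 16)),
               class = "hcs_data_error")
})

test_that("well-separated nuclei are found with accurate centroids", {
  pop <- grid_population(c(200, 350, 500, 275, 420))
  pair <- render_images(pop, image_params(read_noise_sd = 0))
  masks <- segment_nuclei(pair$hoechst)

  expect_equal(nrow(masks$features), 5)
  expect_equal(masks$features$label, 1:5)
  # each generator centre matched by a centroid within 1 px
  for (i in seq_len(5)) {
    d <- sqrt((masks$features$centroid_x - pop$center_x[i])^2 +
                (masks$features$centroid_y - pop$center_y[i])^2)
    expect_lt(min(d), 1)
  }
  # masks are disjoint by construction of the label matrix
  expect_lte(sum(masks$features$area), length(pair$hoechst))
  expect_equal(sum(masks$labels > 0), sum(masks$features$area))
})

test_that("strongly overlapping nuclei merge into one component", {
  pop <- grid_population(c(300, 300))
  pop$center_x <- c(120, 126)  # centres closer than one radius
  pop$center_y <- c(128, 128)
  pair <- render_images(pop, image_params(read_noise_sd = 0))
  masks <- segment_nuclei(pair$hoechst)
  expect_equal(nrow(masks$features), 1)
})

test_that("connectivity 8 joins diagonal pixels; 4 does not", {
  img <- matrix(0, 20, 20)
  img[5:6, 5:6] <- 10   # two 2x2 blocks touching only at a corner
  img[7:8, 7:8] <- 10
  p8 <- segment_params(threshold_method = "fixed", threshold = 5,
                       min_area = 1, exclude_border = FALSE)
  p4 <- segment_params(threshold_method = "fixed", threshold = 5,
                       min_area = 1, connectivity = 4,
                       exclude_border = FALSE)
  expect_equal(nrow(segment_nuclei(img, p8)$features), 1)
  expect_equal(nrow(segment_nuclei(img, p4)$features), 2)
})

test_that("per-nucleus quantification is the mean over the mask", {
  pop <- grid_population(c(200, 350, 500))
  pair <- render_images(pop, image_params(read_noise_sd = 0))
  masks <- segment_nuclei(pair$hoechst)

  flat <- matrix(42, nrow(pair$signal), ncol(pair$signal))
  expect_equal(quantify_nuclei(flat, masks), rep(42, 3))

  vals <- quantify_nuclei(pair$signal, masks)
  # labels run in scan order: match each mask back to its generating cell
  ord <- order(masks$features$centroid_y * 1000 + masks$features$centroid_x)
  for (i in seq_len(3)) {
    cell <- which.min((pop$center_x - masks$features$centroid_x[i])^2 +
                        (pop$center_y - masks$features$centroid_y[i])^2)
    expect_equal(vals[i], pop$signal_level[cell] + 10, tolerance = 0.05)
  }

  blank64 <- matrix(42, 64, 64)
  expect_equal(quantify_nuclei(blank64, segment_nuclei(matrix(1, 64, 64))),
               numeric(0))
  expect_error(quantify_nuclei(matrix(1, 10, 10), masks),
               class = "hcs_data_error")
})

test_that("well aggregation applies the minimum-nucleus rule", {
  a <- aggregate_well(c(10, 20, 30), min_nuclei = 1)
  expect_equal(a$raw_value, 20)
  expect_equal(a$n_nuclei, 3)
  expect_true(a$valid)

  b <- aggregate_well(numeric(0), min_nuclei = 1)
  expect_false(b$valid)
  expect_true(is.na(b$raw_value))

  c_ <- aggregate_well(rnorm(30, 100), min_nuclei = 50)
  expect_false(c_$valid)
  expect_false(is.na(c_$raw_value))
})

test_that("aggregated well means track the truth table (Monte Carlo)", {
  p <- model_params(sigma_plate = 0, lambda_cells = 500)
  fx <- tiny_truth(params = p, seed = 41)
  w <- fx$sample_well
  cells <- simulate_well_cells(w, fx$truth, seed = 77)
  m <- aggregate_well(cells$signal_level, min_nuclei = 50)
  expected <- fx$truth$wells$expected_mean[
    fx$truth$wells$well_id == w$well_id]
  # SD of a single well mean, dominated by the log-normal well noise
  sd_well <- expected * sqrt(exp(p$sigma_well^2) - 1 + p$sigma_cell^2 / 500)
  expect_lt(abs(m$raw_value - expected), 3 * sd_well)
})

test_that("noise-free imaging recovers per-well means within 5%", {
  cfg <- tiny_config(n_genes = 4, sirnas_per_gene = 1, lambda_cells = 20)
  cfg$image <- image_params(read_noise_sd = 0)
  sim <- simulate_screen(cfg, seed = 51)
  active <- sim$layout[sim$layout$content == "sample", ]
  for (i in seq_len(4)) {
    w <- active[i, ]
    cells <- simulate_well_cells(w, sim$truth, seed = 51, positions = TRUE,
                                 image_params = cfg$image)
    pair <- render_images(cells, cfg$image, seed = 1)
    m <- quantify_well(pair, min_nuclei = 1)
    expect_equal(m$n_nuclei, nrow(cells))
    expect_equal(m$raw_value - cfg$image$offset, mean(cells$signal_level),
                 tolerance = 0.05)
  }
})

test_that("background subtraction corrects per plate and flags negatives", {
  wells <- tibble::tibble(
    plate_id = "P01-01",
    well_id = c("A01", "A02", "B01", "B02"),
    content = c("sample", "sample", "background", "background"),
    raw_value = c(100, 10, 18, 22),
    valid = TRUE)
  expect_warning(out <- subtract_background(wells),
                 class = "hcs_negative_corrected")
  expect_equal(out$corrected_value[1], 80)   # 100 - mean(18, 22)
  expect_equal(out$corrected_value[2], -10)  # retained, not clamped
  expect_true(all(is.na(out$corrected_value[3:4])))

  no_bg <- wells[wells$content == "sample", ]
  expect_error(subtract_background(no_bg), class = "hcs_missing_background")

  # equivariance: a constant added to every raw value on a plate cancels
  shifted <- wells
  shifted$raw_value <- shifted$raw_value + 57
  expect_warning(out2 <- subtract_background(shifted))
  expect_equal(out2$corrected_value, out$corrected_value)
})

test_that("global background scope pools all plates", {
  wells <- tibble::tibble(
    plate_id = rep(c("P01-01", "P01-02"), each = 2),
    well_id = rep(c("A01", "B01"), 2),
    content = rep(c("sample", "background"), 2),
    raw_value = c(100, 10, 200, 30),
    valid = TRUE)
  out <- subtract_background(wells, scope = "global")
  expect_equal(out$corrected_value[c(1, 3)], c(100, 200) - 20)
})
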