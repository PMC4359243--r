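test_that("delta-delta-Ct reproduces worked examples", {
  ct <- tibble::tibble(
    sample_id = rep(c("control", "treated"), each = 2),
    gene = rep(c("TGT1", "GAPDH"), 2),
    ct = c(24, 20, 22, 20))
  rq <- delta_delta_ct(ct, "TGT1", "GAPDH", "control")
  expect_equal(rq$rq[rq$sample_id == "control"], 1.0)  # calibrator is 1
  expect_equal(rq$delta_delta_ct[rq$sample_id == "treated"], -2)
  expect_equal(rq$rq[rq$sample_id == "treated"], 4.0)

  # identical Cts across samples: every RQ is 1
  same <- tibble::tibble(sample_id = rep(c("a", "b", "c"), each = 2),
                         gene = rep(c("tgt", "ref"), 3),
                         ct = rep(c(25, 21), 3))
  expect_equal(delta_delta_ct(same, "tgt", "ref", "a")$rq, rep(1, 3))

  # technical replicates enter as their mean
  reps <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    gene = rep(rep(c("tgt", "ref"), each = 2), 2),
    ct = c(24.2, 23.8, 20, 20, 22.5, 21.5, 20.1, 19.9))
  rq <- delta_delta_ct(reps, "tgt", "ref", "a")
  expect_equal(rq$rq[rq$sample_id == "b"], 2^(-(22 - 20 - (24 - 20))))
})

test_that("delta-delta-Ct validates its inputs", {
  ct <- tibble::tibble(sample_id = c("a", "a", "b"),
                       gene = c("tgt", "ref", "tgt"), ct = c(24, 20, 22))
  expect_error(delta_delta_ct(ct, "tgt", "ref", "a"),
               class = "hcs_data_error")  # sample b lacks the reference
  expect_error(delta_delta_ct(ct, "tgt", "ref", "zz"),
               class = "hcs_data_error")  # calibrator absent
  bad <- ct; bad$ct[1] <- 50
  expect_error(delta_delta_ct(bad, "tgt", "ref", "a"),
               class = "hcs_data_error")  # Ct outside (0, 45)
})

test_that("relative quantities are positive and compose additively in log2", {
  set.seed(91)
  ct <- tibble::tibble(
    sample_id = rep(c("a", "b", "c"), each = 2),
    gene = rep(c("tgt", "ref"), 3),
    ct = runif(6, 18, 30))
  rel_a <- delta_delta_ct(ct, "tgt", "ref", "a")
  rel_b <- delta_delta_ct(ct, "tgt", "ref", "b")
  expect_true(all(rel_a$rq > 0))
  # switching calibrator rescales all RQs by one factor (log2-additivity)
  ratio <- log2(rel_a$rq) - log2(rel_b$rq)
  expect_equal(ratio, rep(ratio[1], 3))
})

test_that("the unpaired t-test matches a t-distribution oracle", {
  # identical samples: t = 0, p = 1
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$label, "n.s.")

  # a large clean shift is highly significant
  shift <- ttest_unpaired(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shift$p_value, 0.001)
  expect_equal(shift$label, "***")

  # swap symmetry: t negates, p unchanged
  sw <- ttest_unpaired(c(11, 12, 13), c(1, 2, 3))
  expect_equal(sw$t_statistic, -shift$t_statistic)
  expect_equal(sw$p_value, shift$p_value)

  # pooled-variance closed form, p from the t distribution with n1+n2-2 df
  set.seed(92)
  for (rep in 1:100) {
    x <- rnorm(sample(3:12, 1), 10, 2)
    y <- rnorm(sample(3:12, 1), runif(1, 8, 12), 2)
    got <- ttest_unpaired(x, y)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_oracle <- 2 * pt(-abs(t_oracle), n1 + n2 - 2)
    expect_equal(got$t_statistic, t_oracle, tolerance = 1e-9)
    expect_equal(got$p_value, p_oracle, tolerance = 1e-9)
    # direction agrees with the observed mean difference
    expect_equal(sign(got$t_statistic), sign(mean(x) - mean(y)))
  }

  expect_error(ttest_unpaired(1, c(1, 2)), class = "hcs_parameter_error")
  expect_equal(ttest_unpaired(c(2, 2), c(2, 2))$p_value, 1)
  expect_error(ttest_unpaired(c(2, 2), c(3, 3)), class = "hcs_data_error")
})

test_that("Welch's variant is available behind a flag", {
  set.seed(93)
  x <- rnorm(10, 0, 1); y <- rnorm(5, 1, 4)
  student <- ttest_unpaired(x, y)
  welch <- ttest_unpaired(x, y, var_equal = FALSE)
  expect_equal(student$df, 13)
  expect_lt(welch$df, 13)  # Welch-Satterthwaite df shrink under unequal var
  expect_false(identical(student$p_value, welch$p_value))
})

test_that("asterisk labels follow the strict-inequality convention", {
  expect_equal(significance_stars(0.0004), "***")
  expect_equal(significance_stars(0.004), "**")
  expect_equal(significance_stars(0.04), "*")
  expect_equal(significance_stars(0.05), "n.s.")  # boundary not significant
  expect_equal(significance_stars(c(0.001, 0.01)), c("**", "*"))
  expect_error(significance_stars(-0.1), class = "hcs_parameter_error")
  expect_error(significance_stars(1.1), class = "hcs_parameter_error")
})

test_that("box-plot summaries use linear quantile interpolation", {
  s <- boxplot_summary(0:100)
  expect_equal(s$median, 50)
  expect_equal(s$q1, 25)
  expect_equal(s$q3, 75)
  expect_equal(s$p5, 5)
  expect_equal(s$p95, 95)
  expect_equal(s$n, 101)

  # order statistics: permutation-invariant
  set.seed(94)
  v <- rnorm(200)
  expect_equal(boxplot_summary(sample(v)), boxplot_summary(v))

  # affine equivariance and the ordering invariant
  a <- boxplot_summary(v)
  b <- boxplot_summary(3 + 2 * v)
  expect_equal(unlist(b[, c("p5", "q1", "median", "q3", "p95")]),
               3 + 2 * unlist(a[, c("p5", "q1", "median", "q3", "p95")]))
  expect_true(with(a, p5 <= q1 && q1 <= median && median <= q3 && q3 <= p95))

  const <- suppressWarnings(boxplot_summary(rep(7, 10)))
  expect_true(all(const[, c("p5", "q1", "median", "q3", "p95")] == 7))
  expect_warning(boxplot_summary(1:10), class = "hcs_small_sample")
  expect_error(boxplot_summary(numeric(0)), class = "hcs_parameter_error")
})

test_that("replicate summaries give SD and SEM", {
  s <- summarize_replicates(c(2, 4))
  expect_equal(s$mean, 3)
  expect_equal(s$spread, sqrt(2))          # sample SD, n - 1 denominator
  expect_equal(summarize_replicates(c(2, 4), mode = "sem")$spread, 1)

  set.seed(95)
  v <- rnorm(9)
  expect_equal(summarize_replicates(v, "sd")$spread,
               summarize_replicates(v, "sem")$spread * 3)
  expect_equal(summarize_replicates(rep(5, 4))$spread, 0)
  expect_error(summarize_replicates(3), class = "hcs_parameter_error")
})
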