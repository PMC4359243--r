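#' Relative expression by the delta-delta-Ct method
#'
#' Classic qPCR relative quantification with amplification efficiency fixed
#' at 2: per sample, `dCt = mean(target Ct) - mean(reference Ct)` over
#' technical replicates; `ddCt = dCt - dCt(calibrator)`; relative quantity
#' `RQ = 2^(-ddCt)`. The calibrator sample has `RQ = 1` exactly.
#'
#' @param ct Long-format Ct table: columns `sample_id`, `gene`, `ct`
#'   (cycles, each in (0, 45); technical replicates are repeated rows).
#' @param target_gene Gene of interest.
#' @param reference_gene Normalizer gene (default `"GAPDH"`).
#' @param calibrator_sample Sample all others are expressed relative to
#'   (e.g. the control transfection).
#' @return Tibble with one row per sample: `sample_id`, `delta_ct`,
#'   `delta_delta_ct`, `rq`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("ctrl", "kd"), each = 2),
#'   gene = rep(c("TGT1", "GAPDH"), 2),
#'   ct = c(24, 20, 22, 20))
#' delta_delta_ct(ct, "TGT1", "GAPDH", "ctrl")
delta_delta_ct <- function(ct, target_gene, reference_gene = "GAPDH",
                           calibrator_sample) {
  required <- c("sample_id", "gene", "ct")
  if (!all(required %in% names(ct))) {
    stop_hcs("Ct table needs columns sample_id, gene, ct.", "data_error")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0) || any(ct$ct >= 45)) {
    stop_hcs("Ct values must lie in (0, 45) cycles.", "data_error")
  }
  samples <- unique(ct$sample_id)
  if (!calibrator_sample %in% samples) {
    stop_hcs(sprintf("Calibrator sample '%s' is not in the Ct table.",
                     calibrator_sample), "data_error")
  }
  mean_ct <- function(sample, gene) {
    v <- ct$ct[ct$sample_id == sample & ct$gene == gene]
    if (length(v) == 0) {
      stop_hcs(sprintf("Sample '%s' has no Ct values for gene '%s'.",
                       sample, gene), "data_error")
    }
    mean(v)
  }
  dct <- vapply(samples, function(s) {
    mean_ct(s, target_gene) - mean_ct(s, reference_gene)
  }, numeric(1))
  ddct <- dct - dct[[calibrator_sample]]
  tibble(sample_id = samples, delta_ct = unname(dct),
         delta_delta_ct = unname(ddct), rq = 2^(-unname(ddct)))
}

#' Unpaired two-tailed Student's t-test
#'
#' Classic pooled-variance two-sample t-test with a two-tailed p-value from
#' the t distribution on `n1 + n2 - 2` degrees of freedom, plus the asterisk
#' label from [significance_stars()]. Welch's unequal-variance correction is
#' available behind a flag. When both groups are constant and equal, the
#' test is uninformative and `p = 1` by convention.
#'
#' @param x,y Numeric vectors, each with at least two values.
#' @param var_equal Pooled-variance Student's test (default `TRUE`);
#'   `FALSE` gives Welch's test.
#' @return Object of class `hcs_ttest`: list with `t_statistic`, `df`,
#'   `p_value`, `label`, `n1`, `n2`, `mean_diff`.
#' @export
#' @examples
#' ttest_unpaired(c(1, 2, 3), c(11, 12, 13))
ttest_unpaired <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop_hcs("Each group needs at least two values.", "parameter_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      res <- list(t_statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, label = "n.s.",
                  n1 = length(x), n2 = length(y), mean_diff = 0)
      return(structure(res, class = "hcs_ttest"))
    }
    stop_hcs("Both groups are constant with different means (zero variance).",
             "data_error")
  }
  ht <- t.test(x, y, var.equal = var_equal)
  p <- ht$p.value
  structure(list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = p, label = significance_stars(p),
                 n1 = length(x), n2 = length(y),
                 mean_diff = mean(x) - mean(y)),
            class = "hcs_ttest")
}

#' @export
print.hcs_ttest <- function(x, ...) {
  cat(sprintf("Unpaired two-tailed t-test: t = %.4g, df = %.4g, p = %.3g %s\n",
              x$t_statistic, x$df, x$p_value, x$label))
  cat(sprintf("  n1 = %d, n2 = %d, mean difference = %.4g\n",
              x$n1, x$n2, x$mean_diff))
  invisible(x)
}

#' Asterisk labels for p-values
#'
#' The printed convention with strict inequalities: `"***"` for p < 0.001,
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `"n.s."` otherwise (so
#' p = 0.05 exactly is not significant).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
#' @examples
#' significance_stars(c(0.0004, 0.004, 0.04, 0.05))
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_hcs("p-values must lie in [0, 1].", "parameter_error")
  }
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "n.s.")))
}

#' Box-plot distribution summary
#'
#' Five-number summary used for single-cell intensity distributions: median,
#' first and third quartiles (the box) and the 5th and 95th percentiles (the
#' whiskers). Quantiles use linear interpolation between order statistics
#' (the common default convention).
#'
#' @param values Numeric vector; a warning is issued below 20 values, where
#'   tail percentiles are unstable.
#' @return One-row tibble: `n`, `p5`, `q1`, `median`, `q3`, `p95`.
#' @export
#' @examples
#' boxplot_summary(0:100)
boxplot_summary <- function(values) {
  if (length(values) == 0) {
    stop_hcs("Cannot summarize an empty vector.", "parameter_error")
  }
  if (any(!is.finite(values))) {
    stop_hcs("Values must be finite.", "data_error")
  }
  if (length(values) < 20) {
    rlang::warn("Fewer than 20 values: tail percentiles are unstable.",
                class = "hcs_small_sample")
  }
  q <- quantile(values, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                names = FALSE, type = 7)
  tibble(n = length(values), p5 = q[1], q1 = q[2], median = q[3],
         q3 = q[4], p95 = q[5])
}

#' Mean and spread of replicate measurements
#'
#' Summary used for error bars: the sample mean with either the sample
#' standard deviation (`"sd"`, n - 1 denominator) or the standard error of
#' the mean (`"sem"` = SD / sqrt(n)).
#'
#' @param values Numeric vector with at least two values.
#' @param mode `"sd"` (default) or `"sem"`.
#' @return One-row tibble: `n`, `mean`, `spread`, `mode`.
#' @export
#' @examples
#' summarize_replicates(c(2, 4), mode = "sem")  # mean 3, SEM 1
summarize_replicates <- function(values, mode = c("sd", "sem")) {
  mode <- match.arg(mode)
  if (length(values) < 2) {
    stop_hcs("At least two replicate values are required.", "parameter_error")
  }
  s <- sd(values)
  tibble(n = length(values), mean = mean(values),
         spread = if (mode == "sem") s / sqrt(length(values)) else s,
         mode = mode)
}
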