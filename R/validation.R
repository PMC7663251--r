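#' Bland-Altman agreement between device and reference tilt changes
#'
#' Method-comparison statistics for paired tilt-change measurements: the
#' bias is the mean of device-minus-reference differences, and the limits of
#' agreement are `bias +/- k * SD` of the differences (sample SD, n - 1
#' denominator; `k = 1.96` spans ~95% of differences under normality).
#'
#' @param pairs Data frame of paired measurements with columns
#'   `device_delta_deg` and `reference_delta_deg` (degrees). Rows with a
#'   missing value in either column are dropped.
#' @param k Limits-of-agreement multiplier (default 1.96).
#' @return An object of class `bland_altman` with elements `bias_deg`,
#'   `sd_deg`, `upper_loa_deg`, `lower_loa_deg`, `k`, `n`, and `data`
#'   (per-pair `(mean, difference)` coordinates for plotting). Use [tidy()]
#'   for the coordinates, [glance()] for the one-row summary, and
#'   [ggplot2::autoplot()] for the plot.
#' @examples
#' pairs <- tibble::tibble(device_delta_deg = c(10, -15, 20, 3),
#'                         reference_delta_deg = c(11, -14, 18, 2))
#' glance(bland_altman(pairs))
#' @export
bland_altman <- function(pairs, k = 1.96) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) < 2L) {
    stop("Bland-Altman analysis needs at least 2 complete pairs, got ",
         nrow(pairs), call. = FALSE)
  }
  d <- pairs$device_delta_deg - pairs$reference_delta_deg
  m <- (pairs$device_delta_deg + pairs$reference_delta_deg) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(
    list(
      bias_deg = bias,
      sd_deg = sd_d,
      upper_loa_deg = bias + k * sd_d,
      lower_loa_deg = bias - k * sd_d,
      k = k,
      n = length(d),
      data = tibble::tibble(mean_deg = m, difference_deg = d)
    ),
    class = "bland_altman"
  )
}

#' Limits of agreement from printed summary statistics
#'
#' Reconstructs Bland-Altman limits of agreement when only the bias and SD
#' of differences are available (as in a published report), without the raw
#' pairs.
#'
#' @param bias_deg Mean of device-minus-reference differences (degrees).
#' @param sd_deg Standard deviation of the differences (degrees).
#' @param k Multiplier (default 1.96).
#' @return One-row tibble: `bias_deg`, `sd_deg`, `lower_loa_deg`,
#'   `upper_loa_deg`, `k`.
#' @examples
#' agreement_limits(0.06, 2.74) # upper limit 5.43 to 2 d.p.
#' @export
agreement_limits <- function(bias_deg, sd_deg, k = 1.96) {
  stopifnot(is.finite(bias_deg), is.finite(sd_deg), sd_deg >= 0, k >= 0)
  tibble::tibble(
    bias_deg = bias_deg,
    sd_deg = sd_deg,
    lower_loa_deg = bias_deg - k * sd_deg,
    upper_loa_deg = bias_deg + k * sd_deg,
    k = k
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman agreement (n = %d): bias %.3f deg, SD %.3f deg\n", x$n,
    x$bias_deg, x$sd_deg))
  cat(sprintf("  limits of agreement (k = %.2f): [%.3f, %.3f] deg\n", x$k,
              x$lower_loa_deg, x$upper_loa_deg))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias_deg = x$bias_deg, sd_deg = x$sd_deg,
    lower_loa_deg = x$lower_loa_deg, upper_loa_deg = x$upper_loa_deg,
    k = x$k, n = x$n
  )
}

#' 2x2 screening contingency table and diagnostic metrics
#'
#' `contingency_table()` stores true/false positive/negative counts, with
#' the reference (radiographic) classification as ground truth.
#' `diagnostic_metrics()` derives sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and accuracy `(TP + TN) / total` as proportions; a
#' metric with a zero denominator is reported as `NA` (undefined), never 0.
#'
#' @param tp,fn,fp,tn Non-negative integer counts. `fn` is a reference
#'   positive the device missed; `fp` a reference negative the device
#'   flagged.
#' @return `contingency_table()` returns a `contingency_table` object;
#'   `diagnostic_metrics()` a one-row tibble with `sensitivity`,
#'   `specificity`, `accuracy` (proportions in \[0, 1\]) and the counts.
#' @examples
#' diagnostic_metrics(contingency_table(tp = 11, fn = 2, fp = 1, tn = 19))
#' @export
contingency_table <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("contingency table is empty (all counts zero)", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fn = counts[2], fp = counts[3],
                 tn = counts[4]),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Screening contingency table (reference classification as truth)\n")
  cat(sprintf("                 device +   device -\n"))
  cat(sprintf("  reference +    TP = %-4d  FN = %-4d\n", x$tp, x$fn))
  cat(sprintf("  reference -    FP = %-4d  TN = %-4d\n", x$fp, x$tn))
  invisible(x)
}

#' @rdname contingency_table
#' @param x A `contingency_table`.
#' @param ... Unused.
#' @export
tidy.contingency_table <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fn", "fp", "tn"),
    reference = c("positive", "positive", "negative", "negative"),
    device = c("positive", "negative", "positive", "negative"),
    count = c(x$tp, x$fn, x$fp, x$tn)
  )
}

#' @rdname contingency_table
#' @param table A `contingency_table`.
#' @export
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  total <- table$tp + table$fn + table$fp + table$tn
  tibble::tibble(
    sensitivity = safe_ratio(table$tp, table$tp + table$fn, "sensitivity"),
    specificity = safe_ratio(table$tn, table$tn + table$fp, "specificity"),
    accuracy = safe_ratio(table$tp + table$tn, total, "accuracy"),
    tp = table$tp, fn = table$fn, fp = table$fp, tn = table$tn, n = total
  )
}

#' @rdname contingency_table
#' @export
glance.contingency_table <- function(x, ...) diagnostic_metrics(x)

#' Build a screening contingency table from paired tilt changes
#'
#' Classifies each pair against the mobility threshold: the reference
#' (radiographic) classification is ground truth and the device
#' classification is compared against it.
#'
#' @inheritParams bland_altman
#' @inheritParams classify_mobility
#' @return A [contingency_table].
#' @export
build_contingency <- function(pairs, threshold_deg = 13,
                              mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  pairs <- check_pairs(pairs)
  if (nrow(pairs) == 0L) {
    stop("no complete pairs to classify", call. = FALSE)
  }
  ref_pos <- classify_mobility(pairs$reference_delta_deg, threshold_deg, mode)
  dev_pos <- classify_mobility(pairs$device_delta_deg, threshold_deg, mode)
  contingency_table(
    tp = sum(ref_pos & dev_pos),
    fn = sum(ref_pos & !dev_pos),
    fp = sum(!ref_pos & dev_pos),
    tn = sum(!ref_pos & !dev_pos)
  )
}

#' Correlation between device and reference tilt changes
#'
#' Spearman rank correlation (default, robust to non-linearity in the
#' device-reference relationship) or Pearson correlation of paired tilt
#' changes. The squared coefficient is returned alongside for comparability
#' with R-squared style reporting, whichever method is used.
#'
#' @inheritParams bland_altman
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return One-row tibble: `method`, `coefficient`, `r_squared`, `p_value`,
#'   `n`. A constant input vector yields `NA` coefficients with a warning.
#' @export
tilt_correlation <- function(pairs, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pairs <- check_pairs(pairs)
  n <- nrow(pairs)
  if (n < 3L) {
    stop("correlation needs at least 3 complete pairs, got ", n,
         call. = FALSE)
  }
  if (stats::sd(pairs$device_delta_deg) == 0 ||
      stats::sd(pairs$reference_delta_deg) == 0) {
    warning("constant input vector: correlation undefined", call. = FALSE)
    return(tibble::tibble(method = method, coefficient = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(pairs$device_delta_deg, pairs$reference_delta_deg,
                    method = method, exact = FALSE)
  )
  rho <- unname(ct$estimate)
  tibble::tibble(method = method, coefficient = rho, r_squared = rho^2,
                 p_value = ct$p.value, n = n)
}

#' Distribution of absolute device-reference errors
#'
#' Pools absolute errors `|device - reference|` over all positions and
#' summarises their distribution: median, third quartile (linear
#' interpolation, R quantile type 7 - stated because published quartiles
#' depend on the convention), integer-binned histogram counts, and the
#' maximum-likelihood Poisson rate for the binned errors (the sample mean of
#' errors rounded to the nearest degree), for overlaying a Poisson curve on
#' the histogram.
#'
#' @inheritParams bland_altman
#' @return An object of class `error_distribution`: list with `n`,
#'   `median_deg`, `q3_deg`, `poisson_lambda`, `quantile_type`, `errors`
#'   (the absolute errors) and `histogram` (tibble `error_deg`, `count` over
#'   integer bins).
#' @export
error_distribution <- function(pairs) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) == 0L) {
    stop("no complete pairs", call. = FALSE)
  }
  err <- abs(pairs$device_delta_deg - pairs$reference_delta_deg)
  binned <- round(err)
  bins <- 0:max(binned)
  hist_counts <- tibble::tibble(
    error_deg = bins,
    count = vapply(bins, function(b) sum(binned == b), integer(1))
  )
  structure(
    list(
      n = length(err),
      median_deg = unname(stats::median(err)),
      q3_deg = unname(stats::quantile(err, 0.75, type = 7)),
      poisson_lambda = mean(binned),
      quantile_type = 7L,
      errors = err,
      histogram = hist_counts
    ),
    class = "error_distribution"
  )
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "Absolute error distribution (n = %d): median %.2f deg, Q3 %.2f deg\n",
    x$n, x$median_deg, x$q3_deg))
  cat(sprintf("  Poisson MLE rate over integer bins: %.3f deg\n",
              x$poisson_lambda))
  invisible(x)
}

#' @rdname error_distribution
#' @param x An `error_distribution`.
#' @param ... Unused.
#' @export
tidy.error_distribution <- function(x, ...) x$histogram

#' @rdname error_distribution
#' @export
glance.error_distribution <- function(x, ...) {
  tibble::tibble(n = x$n, median_deg = x$median_deg, q3_deg = x$q3_deg,
                 poisson_lambda = x$poisson_lambda,
                 quantile_type = x$quantile_type)
}

check_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("device_delta_deg", "reference_delta_deg")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L) {
    stop("paired measures are missing column(s): ",
         paste(miss, collapse = ", "),
         "; expected schema includes `device_delta_deg,reference_delta_deg`",
         call. = FALSE)
  }
  keep <- is.finite(pairs$device_delta_deg) &
    is.finite(pairs$reference_delta_deg)
  pairs[keep, , drop = FALSE]
}
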