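test_that("Bland-Altman matches the direct difference-vector formulas", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    pairs <- tibble::tibble(device_delta_deg = rnorm(n, 0, 10),
                            reference_delta_deg = rnorm(n, 0, 10))
    ba <- bland_altman(pairs)
    d <- pairs$device_delta_deg - pairs$reference_delta_deg
    expect_equal(ba$bias_deg, mean(d))
    expect_equal(ba$sd_deg, sd(d)) # sample SD, n-1 denominator
    expect_equal(ba$upper_loa_deg, mean(d) + 1.96 * sd(d))
    expect_equal(ba$lower_loa_deg, mean(d) - 1.96 * sd(d))
    expect_equal(ba$upper_loa_deg - ba$lower_loa_deg, 2 * 1.96 * ba$sd_deg)
    expect_equal(tidy(ba)$difference_deg, d)
  }
})

test_that("identical paired vectors give zero bias and degenerate limits", {
  pairs <- tibble::tibble(device_delta_deg = c(1, 5, -3),
                          reference_delta_deg = c(1, 5, -3))
  ba <- bland_altman(pairs)
  expect_equal(glance(ba)[, c("bias_deg", "sd_deg", "lower_loa_deg",
                              "upper_loa_deg")],
               tibble::tibble(bias_deg = 0, sd_deg = 0, lower_loa_deg = 0,
                              upper_loa_deg = 0))
  expect_error(bland_altman(pairs[1, ]), "at least 2")
})

test_that("limits of agreement reproduce the published step-up example", {
  # bias 0.06, SD 2.74, k = 1.96 -> upper limit 5.43 at 2 d.p.
  loa <- agreement_limits(0.06, 2.74, k = 1.96)
  expect_equal(round(loa$upper_loa_deg, 2), 5.43)
  expect_equal(round(loa$lower_loa_deg, 2), -5.31)
})

test_that("diagnostic metrics agree with integer count arithmetic", {
  # published contingency table: 11/2/1/19
  m <- diagnostic_metrics(contingency_table(tp = 11, fn = 2, fp = 1,
                                            tn = 19))
  expect_equal(round(100 * m$sensitivity, 1), 84.6)
  expect_equal(round(100 * m$specificity, 1), 95.0)
  expect_equal(round(100 * m$accuracy, 1), 90.9)
  # perfect tiny table
  m2 <- diagnostic_metrics(contingency_table(1, 0, 0, 1))
  expect_equal(c(m2$sensitivity, m2$specificity, m2$accuracy), c(1, 1, 1))
  # random tables against the direct ratios
  set.seed(8)
  for (i in 1:20) {
    cnt <- sample(0:15, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    tab <- contingency_table(cnt[1], cnt[2], cnt[3], cnt[4])
    m3 <- suppressWarnings(diagnostic_metrics(tab))
    sens <- if (cnt[1] + cnt[2] == 0) NA_real_ else cnt[1] / (cnt[1] + cnt[2])
    spec <- if (cnt[4] + cnt[3] == 0) NA_real_ else cnt[4] / (cnt[4] + cnt[3])
    expect_equal(m3$sensitivity, sens)
    expect_equal(m3$specificity, spec)
    expect_equal(m3$accuracy, (cnt[1] + cnt[4]) / sum(cnt))
  }
})

test_that("metrics are invariant to scaling all counts and flag zero denominators", {
  m1 <- diagnostic_metrics(contingency_table(3, 1, 2, 5))
  m2 <- diagnostic_metrics(contingency_table(9, 3, 6, 15))
  expect_equal(m1[c("sensitivity", "specificity", "accuracy")],
               m2[c("sensitivity", "specificity", "accuracy")])
  expect_warning(
    m0 <- diagnostic_metrics(contingency_table(0, 0, 1, 3)),
    "sensitivity undefined")
  expect_true(is.na(m0$sensitivity))
  expect_false(is.na(m0$specificity))
})

test_that("contingency construction uses the reference as ground truth", {
  exact <- tibble::tibble(device_delta_deg = c(20, 5, -15, 1),
                          reference_delta_deg = c(20, 5, -15, 1))
  tab <- build_contingency(exact)
  expect_equal(c(tab$fp, tab$fn), c(0, 0))
  expect_equal(c(tab$tp, tab$tn), c(2, 2))
  # boundary bookkeeping: reference 14 is positive, device 12 negative
  one <- tibble::tibble(device_delta_deg = 12, reference_delta_deg = 14)
  tab1 <- build_contingency(one)
  expect_equal(unlist(tab1[c("tp", "fn", "fp", "tn")]),
               c(tp = 0, fn = 1, fp = 0, tn = 0))
  expect_error(build_contingency(exact[0, ]), "no complete pairs")
})

test_that("correlations behave on hand-built vectors", {
  inc <- tibble::tibble(device_delta_deg = 1:6,
                        reference_delta_deg = 2 * (1:6) + 3)
  expect_equal(tilt_correlation(inc)$coefficient, 1)
  expect_equal(tilt_correlation(inc, "pearson")$r_squared, 1)
  rev <- tibble::tibble(device_delta_deg = 1:6,
                        reference_delta_deg = 6:1)
  expect_equal(tilt_correlation(rev)$coefficient, -1)
  # Spearman matches the classic rank formula on a tie-free vector
  set.seed(13)
  x <- sample(1:50, 12)
  y <- sample(1:50, 12)
  pairs <- tibble::tibble(device_delta_deg = x, reference_delta_deg = y)
  d <- rank(x) - rank(y)
  rho_formula <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
  expect_equal(tilt_correlation(pairs)$coefficient, rho_formula,
               tolerance = 1e-12)
  expect_warning(
    out <- tilt_correlation(tibble::tibble(device_delta_deg = c(1, 1, 1),
                                           reference_delta_deg = 1:3)),
    "constant")
  expect_true(is.na(out$coefficient))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(17)
  pairs <- tibble::tibble(device_delta_deg = rnorm(15, 0, 10),
                          reference_delta_deg = rnorm(15, 0, 10))
  base <- tilt_correlation(pairs)$coefficient
  warped <- tibble::tibble(
    device_delta_deg = exp(pairs$device_delta_deg / 10),
    reference_delta_deg = pairs$reference_delta_deg^3
  )
  expect_equal(tilt_correlation(warped)$coefficient, base)
})

test_that("error distribution summaries match hand computations", {
  zero <- tibble::tibble(device_delta_deg = c(3, -2), reference_delta_deg = c(3, -2))
  ed0 <- error_distribution(zero)
  expect_equal(c(ed0$median_deg, ed0$q3_deg), c(0, 0))

  # errors {1,1,2,4}: median 1.5; type-7 Q3 = 2 + 0.25*(4-2) = 2.5
  pairs <- tibble::tibble(device_delta_deg = c(1, -1, 2, 4),
                          reference_delta_deg = c(0, 0, 0, 0))
  ed <- error_distribution(pairs)
  expect_equal(ed$median_deg, 1.5)
  expect_equal(ed$q3_deg, 2.5)
  expect_equal(ed$poisson_lambda, 2) # mean of binned integers {1,1,2,4}
  expect_equal(tidy(ed),
               tibble::tibble(error_deg = 0:4,
                              count = c(0L, 2L, 1L, 0L, 1L)))
})

test_that("autoplot methods return ggplot objects", {
  set.seed(2)
  pairs <- tibble::tibble(device_delta_deg = rnorm(20, 0, 8),
                          reference_delta_deg = rnorm(20, 0, 8))
  expect_s3_class(autoplot(bland_altman(pairs)), "ggplot")
  expect_s3_class(autoplot(error_distribution(pairs)), "ggplot")
  expect_s3_class(plot_stable_window(simulate_trace(5, 1, seed = 1)),
                  "ggplot")
})
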