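# enumeration oracle: probability that N independent founders with green
# probability p span both lineages
enumerate_het <- function(p, N) {
  combos <- expand.grid(rep(list(0:1), N))
  pr <- apply(combos, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  mixed <- apply(combos, 1, function(g) length(unique(g)) == 2)
  sum(pr[mixed])
}

test_that("heterotypic-detection probability matches enumeration", {
  expect_equal(het_probability(0.3, 1), 0)
  expect_equal(het_probability(0.9, 1), 0)
  expect_equal(het_probability(0.5, 2), 0.5)
  expect_equal(het_probability(0.376, 3), enumerate_het(0.376, 3),
               tolerance = 1e-10)
  expect_equal(het_probability(0.376, 3), 0.703872, tolerance = 1e-4)
  for (p in c(0.1, 0.376, 0.5)) {
    for (N in 2:4) {
      expect_equal(het_probability(p, N), enumerate_het(p, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("h is symmetric in p, increasing in N, and saturates at one", {
  p <- c(0.05, 0.2, 0.376, 0.49)
  expect_equal(het_probability(p, 3), het_probability(1 - p, 3))
  for (pp in p) {
    h <- het_probability(pp, 1:12)
    expect_true(all(diff(h) > 0))
  }
  expect_gt(het_probability(0.376, 50), 1 - 1e-8)
  expect_error(het_probability(1.5, 2),
               class = "clonalmosaic_parameter_error")
  expect_error(het_probability(0.5, 0),
               class = "clonalmosaic_parameter_error")
})

test_that("zero observed heterotypic tumors estimate a zero fraction", {
  est <- estimate_multiancestral_fraction(0, 100, p = 0.376, N = 2)
  expect_equal(est$f_hat, 0)
  expect_equal(est$ci_low, 0)
  expect_true(est$ci_high > 0)
})

test_that("the estimate is truncated with a warning when data exceed h", {
  expect_warning(
    est <- estimate_multiancestral_fraction(95, 100, p = 0.376, N = 2),
    "truncated")
  expect_equal(est$f_hat, 1)
})

test_that("estimation is impossible with a single founder", {
  expect_error(estimate_multiancestral_fraction(5, 100, p = 0.376, N = 1),
               class = "clonalmosaic_parameter_error")
})

test_that("the estimate never falls below the raw heterotypic fraction", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:300, 1)
    x <- rbinom(1, n, runif(1, 0.05, 0.6))
    est <- suppressWarnings(
      estimate_multiancestral_fraction(x, n, p = runif(1, 0.1, 0.5),
                                       N = sample(2:4, 1)))
    expect_gte(est$f_hat + 1e-12, x / n)
    expect_lte(est$ci_low, est$f_hat)
    expect_gte(est$ci_high, est$f_hat)
    expect_true(all(c(est$ci_low, est$f_hat, est$ci_high) >= 0 &
                    c(est$ci_low, est$f_hat, est$ci_high) <= 1))
  }
})

test_that("the estimator recovers a planted multi-ancestral fraction", {
  f <- 0.8; p <- 0.376; N <- 2; n <- 5000
  h <- het_probability(p, N)
  set.seed(77)
  f_hats <- vapply(1:200, function(i) {
    x <- rbinom(1, n, f * h)
    estimate_multiancestral_fraction(x, n, p, N)$f_hat
  }, numeric(1))
  expect_lt(abs(mean(f_hats) - f), 0.03)
})

test_that("tidy and glance expose the estimate and its inputs", {
  est <- estimate_multiancestral_fraction(84, 144, p = 0.376, N = 3)
  td <- tidy(est)
  expect_equal(td$estimate, est$f_hat)
  expect_true(td$conf.low <= td$estimate & td$estimate <= td$conf.high)
  gl <- glance(est)
  expect_equal(gl$h, het_probability(0.376, 3))
})

test_that("detection power follows the closed-form binomial model", {
  expect_equal(detection_power(144, 0, 0.376, 2), 0)
  h <- 2 * 0.376 * 0.624
  expect_equal(detection_power(144, 0.01, 0.376, 2),
               1 - (1 - 0.01 * h)^144, tolerance = 1e-12)
  expect_gt(detection_power(288, 0.01, 0.376, 2),
            detection_power(144, 0.01, 0.376, 2))
  expect_gt(detection_power(144, 0.02, 0.376, 2),
            detection_power(144, 0.01, 0.376, 2))
  expect_gt(detection_power(144, 0.01, 0.5, 2),
            detection_power(144, 0.01, 0.376, 2))
  # a cohort of the study's size detects 1-in-100 multi-ancestry reliably
  expect_gt(detection_power(144, 0.01, 0.376, 2), 0.49)
})

test_that("homogeneity test: equal proportions give statistic 0, p = 1", {
  tab <- tibble::tibble(category = c("LGD", "HGD"), heterotypic = c(10, 20),
                        n = c(20, 40))
  res <- compare_proportions(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("homogeneity across published categories is not rejected", {
  res <- compare_proportions(tabulate_architecture(table3_calls()))
  expect_equal(res$method, "chi-square homogeneity")
  expect_gt(res$p.value, 0.05)
  # frozen from the chi-square oracle on (40/65, 21/37, 10/23, 13/19)
  expect_equal(res$statistic, 3.1963, tolerance = 1e-4)
  expect_equal(res$df, 3)
})

test_that("small expected counts engage the exact fallback", {
  tab <- tibble::tibble(category = c("LGD", "HGD"),
                        heterotypic = c(0, 4), n = c(6, 8))
  res <- compare_proportions(tab)
  expect_match(res$method, "Fisher")
  expect_error(compare_proportions(tibble::tibble(
    category = "LGD", heterotypic = 5, n = 10)),
    class = "clonalmosaic_parameter_error")
})

test_that("rank-sum test: identical and textbook samples", {
  res <- rank_sum_test(c(1, 5, 9, 12), c(1, 5, 9, 12))
  expect_equal(res$p.value, 1, tolerance = 1e-9)
  # most extreme of the C(6,3) = 20 rankings: two-sided p = 2/20
  res2 <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res2$p.value, 0.1, tolerance = 1e-12)
  expect_warning(res3 <- rank_sum_test(c(3, 3), c(3, 3, 3)), "tied")
  expect_equal(res3$p.value, 1)
  expect_true(res3$degenerate)
  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "clonalmosaic_parameter_error")
})

test_that("rank-sum test detects the multiplicity shift at study sizes", {
  set.seed(41)
  pvals <- vapply(1:1000, function(i) {
    a <- round(pmax(rnorm(20, 11, 5), 0))
    b <- round(pmax(rnorm(31, 15, 5), 0))
    rank_sum_test(a, b)$p.value
  }, numeric(1))
  expect_gt(stats::median(pvals), 0)
  expect_lt(stats::median(pvals), 0.1)
})

test_that("t-test wrapper matches hand-computed Welch arithmetic", {
  a <- c(0.30, 0.35, 0.40); b <- c(0.50, 0.55, 0.60)
  res <- two_sample_t(a, b)
  se <- sqrt(stats::var(a) / 3 + stats::var(b) / 3)
  t_manual <- (mean(a) - mean(b)) / se
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$estimate, -0.2)
  expect_equal(res$df, 4)  # equal variances and sizes: Welch df = n1+n2-2

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)

  expect_warning(deg <- two_sample_t(c(2, 2), c(2, 2)), "degenerate")
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)
})

test_that("both tests hold their nominal size at the study group sizes", {
  set.seed(53)
  p_t <- vapply(1:1000, function(i) {
    two_sample_t(rnorm(18, 0.376, 0.05), rnorm(15, 0.376, 0.05))$p.value
  }, numeric(1))
  expect_lt(abs(mean(p_t < 0.05) - 0.05), 0.02)

  p_w <- vapply(1:1000, function(i) {
    a <- round(pmax(rnorm(20, 13, 5), 0))
    b <- round(pmax(rnorm(31, 13, 5), 0))
    rank_sum_test(a, b)$p.value
  }, numeric(1))
  expect_lt(abs(mean(p_w < 0.05) - 0.05), 0.02)
})

test_that("null t-test p-values are uniform at the study sample sizes", {
  set.seed(67)
  pvals <- vapply(1:1000, function(i) {
    two_sample_t(rnorm(18, 0.376, 0.05), rnorm(15, 0.376, 0.05))$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Monte-Carlo h agrees with the closed form on independent mosaics", {
  for (p in c(0.2, 0.376)) {
    mc <- het_probability_mc(p, 2, n_tumors = 1200, correlation_length = 0,
                             n_crypts = 2500, seed = 3)
    expect_lt(abs(mc$h_hat - het_probability(p, 2)), 3 * mc$se)
  }
})

test_that("spatial correlation depresses the detection probability", {
  p <- 0.376; N <- 2
  mc_corr <- het_probability_mc(p, N, n_tumors = 1500,
                                correlation_length = 150, n_crypts = 2500,
                                seed = 5)
  expect_lt(mc_corr$h_hat, het_probability(p, N) - 3 * mc_corr$se)
})
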