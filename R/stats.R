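#' Heterotypic-detection probability
#'
#' Probability that a tumor founded by `N` crypts of independent lineage
#' shows both colors: `h = 1 - p^N - (1 - p)^N`, where `p` is the green
#' lineage fraction. A single founder can never be heterotypic (`h = 0`);
#' `h` is symmetric in `p` and `1 - p`, increases with `N`, and tends to 1
#' as `N` grows for `p` strictly inside `(0, 1)`.
#'
#' @param p Green lineage fraction(s) in `[0, 1]`.
#' @param N Founder count(s), integer >= 1. Recycled against `p`.
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' het_probability(0.376, 2)
het_probability <- function(p, N) {
  check_fraction(p, "p")
  if (any(N < 1) || any(N != round(N))) {
    stop_param("`N` must be integer >= 1.", field = "N")
  }
  1 - p^N - (1 - p)^N
}

#' Monte-Carlo heterotypic-detection probability on a spatial lattice
#'
#' Estimates `h` by seeding tumors on a synthetic crypt lattice: founders
#' are recruited within `recruitment_radius` of a uniformly chosen first
#' founder, so spatial lineage correlation (patchy mosaicism) depresses
#' `h` below the independent-lineage closed form [het_probability()].
#' With `correlation_length = 0` the two agree to Monte-Carlo error.
#'
#' @param p Green lineage fraction.
#' @param N Founder count.
#' @param n_tumors Number of simulated tumors (split across lattices).
#' @param correlation_length,n_crypts Lattice parameters
#'   (see [mosaic_params()]).
#' @param recruitment_radius Co-founder recruitment radius (um).
#' @param n_lattices Number of independent lattice realizations; tumors
#'   drawn on the same lattice share its lineage realization, so the
#'   standard error is computed across lattices (cluster-robust).
#' @param seed Integer seed.
#' @return One-row tibble: `h_hat`, `se` (between-lattice Monte-Carlo
#'   standard error), `n_tumors`, `n_lattices`.
#' @export
het_probability_mc <- function(p, N, n_tumors = 2000,
                               correlation_length = 0, n_crypts = 4000,
                               recruitment_radius = 150, n_lattices = 8L,
                               seed = 1L) {
  per <- ceiling(n_tumors / n_lattices)
  lattice_means <- vapply(seq_len(n_lattices), function(l) {
    lat <- generate_lattice(mosaic_params(
      p = p, correlation_length = correlation_length, n_crypts = n_crypts,
      seed = seed + 7919L * l))
    mean(vapply(seq_len(per), function(i) {
      seed_tumor(lat, founder_count = N,
                 recruitment_radius = recruitment_radius,
                 seed = seed + 1000L * l + i)$heterotypic_truth
    }, logical(1)))
  }, numeric(1))
  h <- mean(lattice_means)
  tibble(h_hat = h,
         se = stats::sd(lattice_means) / sqrt(n_lattices),
         n_tumors = as.integer(per * n_lattices),
         n_lattices = as.integer(n_lattices))
}

#' Estimate the true multi-ancestral tumor fraction
#'
#' The observed heterotypic count is modeled `Binomial(n, f * h)`: a tumor
#' is seen as heterotypic only when it is multi-ancestral (probability
#' `f`) *and* its founders span both lineages (probability
#' `h = het_probability(p, N)`). The maximum-likelihood estimate is
#' `f_hat = min(1, x_het / (n * h))`, and the confidence interval inverts
#' the Clopper-Pearson binomial interval for `f * h` and divides by `h`,
#' truncated to `[0, 1]`. The estimate is never below the raw heterotypic
#' fraction: the raw fraction is a lower bound on multi-ancestry.
#'
#' @param x_het Observed heterotypic tumor count.
#' @param n Number of tumors scored.
#' @param p Green lineage fraction.
#' @param N Assumed founder count for multi-ancestral tumors.
#' @param conf_level Confidence level for the interval.
#' @return One-row tibble of class `multiancestral_estimate`: `f_hat`,
#'   `ci_low`, `ci_high`, `method`, plus the inputs and `h`.
#' @export
#' @examples
#' estimate_multiancestral_fraction(84, 144, p = 0.376, N = 2)
estimate_multiancestral_fraction <- function(x_het, n, p, N,
                                             conf_level = 0.95) {
  if (x_het < 0 || x_het > n) {
    stop_param("`x_het` must lie in [0, n].", field = "x_het")
  }
  h <- het_probability(p, N)
  if (h <= 0) {
    abort("Detection probability h(p, N) is zero; f is inestimable.",
          class = "clonalmosaic_parameter_error")
  }
  raw <- x_het / n
  f_hat <- min(1, raw / h)
  if (raw > h) {
    warn(sprintf(
      "Observed heterotypic fraction %.3f exceeds detection probability %.3f; estimate truncated at 1 (model inconsistency).",
      raw, h))
  }
  a <- 1 - conf_level
  q_low <- if (x_het == 0) 0 else qbeta(a / 2, x_het, n - x_het + 1)
  q_high <- if (x_het == n) 1 else qbeta(1 - a / 2, x_het + 1, n - x_het)
  out <- tibble(
    f_hat = f_hat,
    ci_low = min(1, q_low / h),
    ci_high = min(1, q_high / h),
    method = "binomial inversion, Clopper-Pearson",
    x_het = as.integer(x_het), n = as.integer(n), p = p, N = as.integer(N),
    h = h, conf_level = conf_level)
  class(out) <- c("multiancestral_estimate", class(out))
  out
}

#' Power to detect multi-ancestral tumors
#'
#' Probability of observing at least `min_detected` heterotypic tumors
#' among `n` scored, when a fraction `f` of tumors is multi-ancestral and
#' each such tumor is detected with probability `h = het_probability(p,
#' N)`: `1 - pbinom(min_detected - 1, n, f * h)`. Monotone increasing in
#' `n`, `f`, and `h`.
#'
#' @param n Number of tumors scored.
#' @param f True multi-ancestral fraction.
#' @param p Green lineage fraction.
#' @param N Founder count of multi-ancestral tumors.
#' @param min_detected Minimum number of heterotypic tumors to call a
#'   detection (default 1).
#' @return Numeric power value(s).
#' @export
#' @examples
#' detection_power(n = 144, f = 0.01, p = 0.376, N = 2)
detection_power <- function(n, f, p, N, min_detected = 1) {
  check_fraction(f, "f")
  h <- het_probability(p, N)
  1 - pbinom(min_detected - 1, n, f * h)
}

#' Homogeneity test of the heterotypic fraction across categories
#'
#' Chi-square test that the heterotypic proportion is the same in every
#' pathological category, falling back to Fisher's exact test
#' (Freeman-Halton for more than two categories) when any expected cell
#' count is below 5.
#'
#' @param table An [tabulate_architecture()] result, or a tibble with
#'   columns `heterotypic` and `n` (one row per category; a `"Total"` row
#'   is dropped automatically).
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
compare_proportions <- function(table) {
  tab <- as_tibble(table)
  if ("category" %in% names(tab)) tab <- tab[tab$category != "Total", ]
  if (nrow(tab) < 2) {
    stop_param("at least two categories are required.", field = "table")
  }
  het <- tab$heterotypic
  non <- tab$n - het
  m <- cbind(het, non)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(m)
    return(tibble(statistic = NA_real_, df = NA_real_, p.value = ft$p.value,
                  method = "Fisher exact (Freeman-Halton)"))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value, method = "chi-square homogeneity")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Wrapper used for per-mouse tumor multiplicity comparisons: exact for
#' small tie-free samples, normal approximation with tie correction
#' otherwise. Fully tied degenerate samples give `p = 1` with a warning.
#'
#' @param a,b Numeric samples (e.g. per-mouse tumor counts).
#' @return One-row tibble: `statistic` (W), `p.value`, `method`,
#'   `degenerate`.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_param("both samples must be non-empty.")
  }
  if (length(unique(c(a, b))) == 1) {
    warn("All observations tied; rank-sum test is degenerate (p = 1).")
    return(tibble(statistic = NA_real_, p.value = 1,
                  method = "Wilcoxon rank sum", degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
         method = "Wilcoxon rank sum", degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Wrapper used for green-fraction stability comparisons (e.g. colon
#' green percentage in young versus aged mice). Both-samples-constant
#' input is degenerate and flagged rather than an error.
#'
#' @param a,b Numeric samples (e.g. per-mouse green fractions).
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p.value`, `method`, `degenerate`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop_param("each sample must contain at least two values.")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    warn("Both samples have zero variance; t-test is degenerate.")
    return(tibble(estimate = mean(a) - mean(b), statistic = NA_real_,
                  df = NA_real_, p.value = if (mean(a) == mean(b)) 1 else NA_real_,
                  method = "Welch two-sample t", degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  tibble(estimate = unname(diff(rev(tt$estimate))),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, method = "Welch two-sample t",
         degenerate = FALSE)
}
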