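# small helper: a label map with everything tissue-red except given blobs
blob_map <- function(dim = c(120L, 120L), green_blobs = list(),
                     pixel_size = 10) {
  lab <- matrix(1L, dim[1], dim[2])
  for (b in green_blobs) {
    lab[b$x, b$y] <- 2L
  }
  label_map(lab, pixel_size)
}

full_mask <- function(lm) matrix(TRUE, nrow(lm$labels), ncol(lm$labels))

test_that("pure single-lineage tumors are homotypic with fraction one", {
  lm <- blob_map()
  reg <- tumor_region("t1", full_mask(lm), "LGD")
  call <- classify_tumor(lm, reg)
  expect_equal(call$phenotype, "homotypic_red")
  expect_equal(call$red_area_fraction, 1)
  expect_equal(call$n_discrete_clones, 1L)
})

test_that("a sizeable minority clone makes the tumor heterotypic", {
  lm <- blob_map(green_blobs = list(list(x = 1:48, y = 1:120)))  # 40% green
  reg <- tumor_region("t2", full_mask(lm), "HGD")
  call <- classify_tumor(lm, reg)
  expect_equal(call$phenotype, "heterotypic")
  expect_equal(call$red_area_fraction, 0.6)
  expect_gte(call$n_discrete_clones, 2L)
})

test_that("a mask with no tissue yields a flagged undeterminable call", {
  lab <- matrix(0L, 20, 20)
  lab[15:20, 15:20] <- 1L
  lm <- label_map(lab, 10)
  mask <- matrix(FALSE, 20, 20)
  mask[1:5, 1:5] <- TRUE
  reg <- tumor_region("t3", mask, "LGD")
  expect_warning(call <- classify_tumor(lm, reg), "undeterminable")
  expect_true(call$flagged)
  expect_true(is.na(call$phenotype))
})

test_that("raising min_clone_area never converts homotypic to heterotypic", {
  for (s in 1:8) {
    lab <- random_label_matrix(s, dim = c(60L, 60L), p_green = 0.2)
    lab[lab == 0L] <- 1L
    lm <- label_map(lab, 5)
    reg <- tumor_region("t", full_mask(lm), "LGD")
    areas <- c(500, 2000, 8000, 32000)
    phen <- vapply(areas, function(a) {
      classify_tumor(lm, reg, min_clone_area = a)$phenotype
    }, character(1))
    het <- phen == "heterotypic"
    # once lost, heterotypic status never returns at larger thresholds
    expect_true(all(diff(het) <= 0))
  }
})

test_that("discrete clone counting follows the separation rule", {
  # one contiguous green blob in a red tumor -> 2 clones
  lm1 <- blob_map(green_blobs = list(list(x = 10:20, y = 10:20)))
  reg <- tumor_region("t", full_mask(lm1), "LGD")
  expect_equal(count_discrete_clones(lm1, reg), 2L)

  # three green blobs pairwise > 100 um apart -> 3 green + 1 red
  lm3 <- blob_map(green_blobs = list(
    list(x = 1:10, y = 1:10), list(x = 60:70, y = 1:10),
    list(x = 1:10, y = 60:70)))
  expect_equal(count_discrete_clones(lm3, tumor_region("t", full_mask(lm3), "LGD"),
                                     min_separation = 100), 4L)

  # two green blobs 50 um apart merge under a 100 um separation rule
  lm2 <- blob_map(green_blobs = list(
    list(x = 10:20, y = 10:20), list(x = 26:36, y = 10:20)))  # 5 px = 50 um gap
  expect_equal(count_discrete_clones(lm2, tumor_region("t", full_mask(lm2), "LGD"),
                                     min_separation = 100), 2L)
  # and stay discrete when the rule is tightened below the gap
  expect_equal(count_discrete_clones(lm2, tumor_region("t", full_mask(lm2), "LGD"),
                                     min_separation = 30), 3L)
})

test_that("homotypic tumors count a single clone", {
  lm <- blob_map()
  expect_equal(count_discrete_clones(lm, tumor_region("t", full_mask(lm), "LGD")), 1L)
})

test_that("architecture tabulation reproduces the published counts", {
  t1 <- tabulate_architecture(table1_distal_calls())
  row <- t1[t1$category == "LGD", ]
  expect_equal(row$n, 63L)
  expect_equal(row$heterotypic, 32L)
  expect_equal(row$pct_heterotypic, 51)
  expect_equal(row$pct_homotypic_red, 38)
  expect_equal(row$pct_homotypic_green, 11)

  t3 <- tabulate_architecture(table3_calls())
  expect_equal(t3$pct_heterotypic[match(c("LGD", "HGD", "intramucosal",
                                          "invasive", "Total"),
                                        t3$category)],
               c(62, 57, 43, 68, 58))
  tot <- t3[t3$category == "Total", ]
  expect_equal(tot$n, 144L)
  expect_equal(c(tot$heterotypic, tot$homotypic_red, tot$homotypic_green),
               c(84L, 57L, 3L))
  expect_equal(c(tot$pct_homotypic_red, tot$pct_homotypic_green), c(40, 2))
})

test_that("tabulation totals always partition the input calls", {
  calls <- table3_calls()
  tab <- tabulate_architecture(calls)
  body <- tab[tab$category != "Total", ]
  expect_equal(sum(body$n), nrow(calls))
  expect_equal(body$heterotypic + body$homotypic_red + body$homotypic_green,
               body$n)
})

test_that("empty call lists give an all-zero table", {
  empty <- tibble::tibble(tumor_id = character(), phenotype = character(),
                          category = character())
  tab <- tabulate_architecture(empty)
  expect_equal(nrow(tab), 1L)  # just the Total row
  expect_equal(tab$n, 0L)
})

test_that("unknown categories are a validation error", {
  calls <- tibble::tibble(tumor_id = "x", phenotype = "heterotypic",
                          category = "Adenoma")
  expect_error(tabulate_architecture(calls),
               class = "clonalmosaic_parameter_error")
})

test_that("simultaneous invasion rate matches planted annotations", {
  tumors <- tibble::tibble(
    category = rep("invasive", 15),
    invading_lineages = c(rep("RED;GREEN", 2), rep("RED", 10),
                          rep("GREEN", 3)))
  rate <- simultaneous_invasion_rate(tumors)
  expect_equal(rate$n_invasive, 15L)
  expect_equal(rate$n_simultaneous, 2L)
  expect_equal(rate$percent, 13)

  none <- tibble::tibble(category = rep("invasive", 4),
                         invading_lineages = rep("RED", 4))
  expect_equal(simultaneous_invasion_rate(none)$fraction, 0)

  expect_warning(
    out <- simultaneous_invasion_rate(
      tibble::tibble(category = "LGD", invading_lineages = "RED")),
    "invasive")
  expect_true(out$flagged)
})

test_that("noise-free calls match founder truth on simulated cohorts", {
  calls <- dplyr::bind_rows(
    simulate_scored_cohort(1, n_tumors = 25, noise_sd = 0),
    simulate_scored_cohort(2, n_tumors = 25, noise_sd = 0))
  expect_gte(nrow(calls), 40)
  expect_equal(calls$phenotype == "heterotypic", calls$heterotypic_truth)
})

test_that("default-noise calls match founder truth in >= 98% of tumors", {
  calls <- purrr::map_dfr(1:20, simulate_scored_cohort, n_tumors = 25)
  expect_gte(nrow(calls), 500)
  acc <- mean((calls$phenotype == "heterotypic") == calls$heterotypic_truth)
  expect_gte(acc, 0.98)
})
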