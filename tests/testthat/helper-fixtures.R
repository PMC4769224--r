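# Shared fixtures and independent oracles for the test suite.

# O(n^2) brute-force nearest-opposite-lineage distances, the independent
# oracle for distance_map(): for every tissue pixel, scan all pixels of
# the opposite lineage.
brute_force_distance_map <- function(labels_matrix, pixel_size = 1) {
  nx <- nrow(labels_matrix); ny <- ncol(labels_matrix)
  out <- matrix(NA_real_, nx, ny)
  red <- which(labels_matrix == 1L, arr.ind = TRUE)
  green <- which(labels_matrix == 2L, arr.ind = TRUE)
  if (nrow(red) == 0 || nrow(green) == 0) {
    out[labels_matrix != 0L] <- Inf
    return(out)
  }
  for (k in seq_len(nrow(red))) {
    d2 <- (green[, 1] - red[k, 1])^2 + (green[, 2] - red[k, 2])^2
    out[red[k, 1], red[k, 2]] <- sqrt(min(d2))
  }
  for (k in seq_len(nrow(green))) {
    d2 <- (red[, 1] - green[k, 1])^2 + (red[, 2] - green[k, 2])^2
    out[green[k, 1], green[k, 2]] <- sqrt(min(d2))
  }
  out * pixel_size
}

# random trinary label matrix with roughly p_tissue tissue and p_green of
# tissue green
random_label_matrix <- function(seed, dim = c(64L, 64L), p_green = 0.4,
                                p_tissue = 0.85) {
  set.seed(seed)
  tissue <- matrix(runif(prod(dim)) < p_tissue, dim[1], dim[2])
  lab <- matrix(0L, dim[1], dim[2])
  lab[tissue] <- ifelse(runif(sum(tissue)) < p_green, 2L, 1L)
  lab
}

# Per-tumor call tables transcribed from the study's published
# architecture tables (used to check the tabulation arithmetic).
make_calls <- function(category, n_het, n_red, n_green, prefix) {
  phen <- c(rep("heterotypic", n_het), rep("homotypic_red", n_red),
            rep("homotypic_green", n_green))
  tibble::tibble(
    tumor_id = sprintf("%s%03d", prefix, seq_along(phen)),
    phenotype = phen, category = category)
}

table1_distal_calls <- function() {
  make_calls("LGD", 32, 24, 7, "D")
}

table3_calls <- function() {
  dplyr::bind_rows(
    make_calls("LGD", 40, 23, 2, "L"),
    make_calls("HGD", 21, 15, 1, "H"),
    make_calls("intramucosal", 10, 13, 0, "M"),
    make_calls("invasive", 13, 6, 0, "I"))
}

# Simulate a cohort of non-overlapping tumors on one lattice and return
# truth plus classification calls against the binarized render.
simulate_scored_cohort <- function(seed, n_tumors = 25, n_crypts = 1200,
                                   p = 0.376, correlation_length = 50,
                                   noise_sd = 0.08,
                                   founder_counts = 1:4,
                                   recruitment_radius = 120) {
  lat <- generate_lattice(mosaic_params(
    p = p, correlation_length = correlation_length, n_crypts = n_crypts,
    seed = seed))
  tumors <- list()
  centres <- matrix(numeric(0), ncol = 2)
  k <- 0L
  attempt <- 0L
  set.seed(seed + 7000L)
  fc_stream <- sample(founder_counts, 10 * n_tumors, replace = TRUE)
  while (k < n_tumors && attempt < 10L * n_tumors) {
    attempt <- attempt + 1L
    tum <- tryCatch(
      seed_tumor(lat, founder_count = fc_stream[attempt],
                 recruitment_radius = recruitment_radius,
                 seed = seed * 10000L + attempt),
      error = function(e) NULL)
    if (is.null(tum)) next
    ctr <- c(tum$founder_x[1], tum$founder_y[1])
    if (nrow(centres) > 0 &&
        any(sqrt(rowSums(sweep(centres, 2, ctr)^2)) <
            2.2 * recruitment_radius)) next
    k <- k + 1L
    centres <- rbind(centres, ctr)
    tumors[[k]] <- tum
  }
  img <- render_whole_mount(lat, tumors, noise_sd = noise_sd,
                            pixel_size = 5, seed = seed + 1L)
  labels <- binarize(img)
  calls <- purrr::map_dfr(seq_along(tumors), function(i) {
    reg <- tumor_region(sprintf("T%03d", i), img$tumor_id == i, "LGD")
    classify_tumor(labels, reg)
  })
  calls$heterotypic_truth <- purrr::map_lgl(tumors, "heterotypic_truth")
  calls$founder_count <- purrr::map_int(tumors, "founder_count")
  calls
}
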