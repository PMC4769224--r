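#' Default pipeline configuration
#'
#' @param seed Master seed for the run.
#' @param out_dir Output directory (created if needed).
#' @param ... Named overrides of nested fields, e.g.
#'   `lattice = list(p = 0.12)`.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("clonalmosaic_run"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    lattice = list(p = 0.376, correlation_length = 100, n_crypts = 1500,
                   crypt_radius = 25),
    tumors = list(n_tumors = 12, founder_counts = 1:4,
                  recruitment_radius = 150,
                  category_probs = c(LGD = 0.45, HGD = 0.26,
                                     intramucosal = 0.16, invasive = 0.13)),
    render = list(noise_sd = 0.08, illumination_gradient = 0.2,
                  pixel_size = 5),
    binarize = list(tissue_min_intensity = 0.5),
    classify = list(min_clone_area = pi * 25^2, min_separation = 100),
    stats = list(N_assumed = 2L)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  check_fraction(cfg$lattice$p, "lattice$p")
  check_positive(cfg$lattice$correlation_length, "lattice$correlation_length",
                 strict = FALSE)
  check_positive(cfg$lattice$n_crypts, "lattice$n_crypts")
  check_positive(cfg$render$pixel_size, "render$pixel_size")
  check_positive(cfg$render$noise_sd, "render$noise_sd", strict = FALSE)
  check_positive(cfg$classify$min_clone_area, "classify$min_clone_area")
  check_positive(cfg$classify$min_separation, "classify$min_separation",
                 strict = FALSE)
  check_positive(cfg$tumors$recruitment_radius, "tumors$recruitment_radius")
  if (cfg$stats$N_assumed < 1) {
    stop_param("`stats$N_assumed` must be >= 1.", field = "stats$N_assumed")
  }
  invisible(cfg)
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Executes simulate -> binarize -> patch statistics -> classify ->
#' tabulate -> stats on a synthetic whole mount, writing all outputs
#' (label-map TIFF, calls CSV, architecture CSV, patch-stats CSV, stats
#' JSON) plus a manifest of every parameter into `config$out_dir`.
#' Identical configuration and seed give bit-identical CSV outputs.
#'
#' @param config A [pipeline_config()] list.
#' @return A run report: list with `stages` (tibble of stage names and
#'   timings), `outputs` (file paths), `calls`, `architecture`,
#'   `patch_stats`, `estimate`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  times <- numeric()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "clonalmosaic_stage_error", parent = e)
    })
    stages <<- c(stages, name)
    times <<- c(times, as.numeric(Sys.time() - t0, units = "secs"))
    val
  }

  sim <- tick("simulate", {
    lat <- generate_lattice(mosaic_params(
      p = config$lattice$p,
      correlation_length = config$lattice$correlation_length,
      n_crypts = config$lattice$n_crypts,
      crypt_radius = config$lattice$crypt_radius,
      seed = config$seed))
    n_t <- config$tumors$n_tumors
    set.seed(config$seed + 1L)
    fc <- sample(config$tumors$founder_counts, 20 * n_t, replace = TRUE)
    cats <- sample(names(config$tumors$category_probs), n_t, replace = TRUE,
                   prob = config$tumors$category_probs)
    # place tumors by rejection so blobs do not overlap and every tumor
    # keeps its own truth region
    rr <- config$tumors$recruitment_radius
    tumors <- list()
    centres <- matrix(numeric(0), ncol = 2)
    attempt <- 0L
    while (length(tumors) < n_t && attempt < 20L * n_t) {
      attempt <- attempt + 1L
      tum <- tryCatch(
        seed_tumor(lat, founder_count = fc[attempt],
                   recruitment_radius = rr,
                   seed = config$seed * 1000L + attempt),
        error = function(e) NULL)
      if (is.null(tum)) next
      ctr <- c(tum$founder_x[1], tum$founder_y[1])
      if (nrow(centres) > 0 &&
          any(sqrt(rowSums(sweep(centres, 2, ctr)^2)) < 2.2 * rr)) next
      centres <- rbind(centres, ctr)
      tumors[[length(tumors) + 1L]] <- tum
    }
    if (length(tumors) < n_t) {
      abort(sprintf(
        "Could only place %d of %d non-overlapping tumors; enlarge the lattice or reduce n_tumors.",
        length(tumors), n_t), class = "clonalmosaic_geometry_error")
    }
    img <- render_whole_mount(
      lat, tumors, noise_sd = config$render$noise_sd,
      illumination_gradient = config$render$illumination_gradient,
      pixel_size = config$render$pixel_size, seed = config$seed + 2L)
    list(lattice = lat, tumors = tumors, categories = cats, image = img)
  })

  labels <- tick("binarize", binarize(
    sim$image, tissue_min_intensity = config$binarize$tissue_min_intensity))

  patch <- tick("patchsize", patch_size(labels))

  calls <- tick("classify", {
    regions <- purrr::map(seq_along(sim$tumors), function(i) {
      tum <- sim$tumors[[i]]
      lin <- unique(tum$founder_lineages)
      tumor_region(
        tumor_id = sprintf("T%03d", i),
        mask = sim$image$tumor_id == i,
        category = sim$categories[i],
        tract_section = 5L,
        invading_lineages = if (sim$categories[i] == "invasive") lin)
    })
    calls <- purrr::map_dfr(regions, function(r) classify_tumor(
      labels, r, min_clone_area = config$classify$min_clone_area,
      min_separation = config$classify$min_separation))
    calls$category <- sim$categories
    calls$founder_count_truth <-
      purrr::map_int(sim$tumors, "founder_count")
    calls$heterotypic_truth <-
      purrr::map_lgl(sim$tumors, "heterotypic_truth")
    attr(calls, "regions") <- regions
    calls
  })

  arch <- tick("tabulate", tabulate_architecture(calls))

  stats_out <- tick("stats", {
    x_het <- sum(calls$phenotype == "heterotypic", na.rm = TRUE)
    est <- estimate_multiancestral_fraction(
      x_het, nrow(calls), p = config$lattice$p, N = config$stats$N_assumed)
    inv <- simultaneous_invasion_rate(attr(calls, "regions"))
    list(estimate = est, invasion = inv)
  })

  out <- list(
    labels_tif = file.path(config$out_dir, "labels.tif"),
    calls_csv = file.path(config$out_dir, "calls.csv"),
    architecture_csv = file.path(config$out_dir, "architecture.csv"),
    patch_csv = file.path(config$out_dir, "patch_stats.csv"),
    stats_json = file.path(config$out_dir, "stats.json"),
    manifest_json = file.path(config$out_dir, "manifest.json"))
  write_label_map(labels, out$labels_tif)
  write_calls(calls[, setdiff(names(calls), "regions")], out$calls_csv)
  write_table(arch, out$architecture_csv)
  write.csv(as.data.frame(patch), out$patch_csv, row.names = FALSE)
  jsonlite::write_json(
    list(estimate = as.list(as.data.frame(stats_out$estimate)),
         invasion = as.list(as.data.frame(stats_out$invasion))),
    out$stats_json, auto_unbox = TRUE, digits = NA)

  cfg_flat <- config
  cfg_flat$tumors$category_probs <- as.list(cfg_flat$tumors$category_probs)
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("clonalmosaic")),
         config = unclass(cfg_flat),
         stages = stages),
    out$manifest_json, auto_unbox = TRUE, digits = NA)

  list(
    stages = tibble(stage = stages, seconds = round(times, 3)),
    outputs = out,
    calls = calls,
    architecture = arch,
    patch_stats = patch,
    estimate = stats_out$estimate,
    invasion = stats_out$invasion)
}
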