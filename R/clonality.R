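#' Construct a tumor region
#'
#' @param tumor_id Character identifier.
#' @param mask Logical matrix, same shape as the label map it will be
#'   scored against; `TRUE` inside the tumor.
#' @param category Pathological category: one of `"LGD"`, `"HGD"`,
#'   `"intramucosal"`, `"invasive"`.
#' @param tract_section Integer 1-5.
#' @param invading_lineages For invasive tumors, character vector subset
#'   of `c("RED", "GREEN")` giving the lineages seen invading.
#' @return A list of class `tumor_region`.
#' @export
tumor_region <- function(tumor_id, mask, category, tract_section = 5L,
                         invading_lineages = NULL) {
  if (!category %in% PATH_CATEGORIES) {
    stop_param(sprintf("unknown category '%s'; expected one of %s.",
                       category, paste(PATH_CATEGORIES, collapse = ", ")),
               field = "category")
  }
  if (!is.logical(mask) || !any(mask)) {
    stop_param("`mask` must be a logical matrix with at least one TRUE pixel.")
  }
  if (!is.null(invading_lineages) &&
      !all(invading_lineages %in% c("RED", "GREEN"))) {
    stop_param("`invading_lineages` must be a subset of c('RED', 'GREEN').")
  }
  structure(
    list(tumor_id = as.character(tumor_id), mask = mask, category = category,
         tract_section = as.integer(tract_section),
         invading_lineages = invading_lineages),
    class = "tumor_region"
  )
}

# 8-connected component labeling of a logical matrix via union-find
label_components8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nx, ny)
  if (length(idx) == 0) return(lab)
  parent <- seq_along(idx)
  pos <- matrix(0L, nx, ny)
  pos[idx] <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  rows <- ((idx - 1L) %% nx) + 1L
  cols <- ((idx - 1L) %/% nx) + 1L
  offs <- rbind(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  for (k in seq_along(idx)) {
    r <- rows[k]; cc <- cols[k]
    for (o in 1:4) {
      rr <- r + offs[o, 1L]; cj <- cc + offs[o, 2L]
      if (rr >= 1L && rr <= nx && cj >= 1L && cj <= ny && mask[rr, cj]) {
        a <- find(k); b <- find(pos[rr, cj])
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Count discrete clone territories within a tumor
#'
#' Counts 8-connected components of minority-lineage tissue within the
#' tumor mask, merging components whose minimal pixel-to-pixel Euclidean
#' gap is below `min_separation` (discrete clones must be separated by at
#' least that distance, by default 100 um, about one to two crypt
#' diameters), then adds one for the majority lineage.
#'
#' @param labels A [label_map()].
#' @param tumor A [tumor_region()].
#' @param min_separation Minimum boundary gap (micrometres) for two
#'   minority components to count as discrete clones.
#' @return Integer clone count (1 for a homotypic tumor).
#' @export
count_discrete_clones <- function(labels, tumor, min_separation = 100) {
  stopifnot(inherits(labels, "label_map"), inherits(tumor, "tumor_region"))
  check_positive(min_separation, "min_separation", strict = FALSE)
  lab <- labels$labels
  if (!all(dim(tumor$mask) == dim(lab))) {
    stop_param("tumor mask shape must match the label map.")
  }
  n_red <- sum(tumor$mask & lab == LBL_RED)
  n_green <- sum(tumor$mask & lab == LBL_GREEN)
  if (n_red == 0 || n_green == 0) return(1L)

  minority <- if (n_green <= n_red) LBL_GREEN else LBL_RED
  comp <- label_components8(tumor$mask & lab == minority)
  k <- max(comp)
  if (k == 1L) return(2L)

  # pairwise minimal pixel-centre gaps via one distance map per component
  gap <- matrix(Inf, k, k)
  px <- labels$pixel_size
  for (i in seq_len(k - 1L)) {
    d_i <- EBImage::imageData(
      EBImage::distmap(matrix(as.numeric(comp != i), nrow(lab), ncol(lab))))
    for (j in (i + 1L):k) {
      gap[i, j] <- gap[j, i] <- min(d_i[comp == j]) * px
    }
  }
  # merge components closer than min_separation (single-linkage closure)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (gap[i, j] < min_separation) {
      a <- find(i); b <- find(j)
      if (a != b) parent[a] <- b
    }
  }
  n_minority <- length(unique(vapply(seq_len(k), find, integer(1))))
  n_minority + 1L
}

#' Classify a tumor's clonal architecture
#'
#' A tumor is called heterotypic when the tissue area of each lineage
#' within its mask reaches `min_clone_area`; otherwise it is homotypic
#' with the dominant lineage. The default minimum clone area is one crypt
#' (pi * 25^2 um^2): dysplastic crypts are wholly one color, so one crypt
#' is the smallest credible clone.
#'
#' @inheritParams count_discrete_clones
#' @param min_clone_area Minimum per-lineage tissue area (um^2) required
#'   to count a lineage as a clone.
#' @param min_separation Passed to [count_discrete_clones()].
#' @return One-row tibble (`tumor_id`, `phenotype`, `red_area_fraction`,
#'   `n_discrete_clones`, `minority_clone_area`, `flagged`). A mask with
#'   no tissue yields phenotype `NA` with `flagged = TRUE` and a warning.
#' @export
classify_tumor <- function(labels, tumor, min_clone_area = pi * 25^2,
                           min_separation = 100) {
  stopifnot(inherits(labels, "label_map"), inherits(tumor, "tumor_region"))
  check_positive(min_clone_area, "min_clone_area")
  lab <- labels$labels
  if (!all(dim(tumor$mask) == dim(lab))) {
    stop_param("tumor mask shape must match the label map.")
  }
  px2 <- labels$pixel_size^2
  red_area <- sum(tumor$mask & lab == LBL_RED) * px2
  green_area <- sum(tumor$mask & lab == LBL_GREEN) * px2
  total <- red_area + green_area
  if (total == 0) {
    warn(sprintf("Tumor '%s' contains no tissue; call is undeterminable.",
                 tumor$tumor_id))
    return(tibble(tumor_id = tumor$tumor_id, phenotype = NA_character_,
                  red_area_fraction = NA_real_,
                  n_discrete_clones = NA_integer_,
                  minority_clone_area = NA_real_, flagged = TRUE))
  }
  phenotype <- if (red_area >= min_clone_area && green_area >= min_clone_area) {
    "heterotypic"
  } else if (red_area >= green_area) {
    "homotypic_red"
  } else {
    "homotypic_green"
  }
  n_clones <- if (phenotype == "heterotypic") {
    count_discrete_clones(labels, tumor, min_separation)
  } else 1L
  tibble(
    tumor_id = tumor$tumor_id,
    phenotype = phenotype,
    red_area_fraction = red_area / total,
    n_discrete_clones = n_clones,
    minority_clone_area = min(red_area, green_area),
    flagged = FALSE
  )
}

#' Tabulate clonal architecture by pathological category
#'
#' Builds the architecture table: counts of heterotypic, homotypic-red and
#' homotypic-green tumors per pathological category with integer-rounded
#' percentages, plus a totals row.
#'
#' @param calls Tibble of per-tumor calls ([classify_tumor()] rows, or any
#'   tibble with `tumor_id` and `phenotype`). A `category` column is used
#'   if present.
#' @param tumors Optional list of [tumor_region()] objects or a tibble
#'   with `tumor_id` and `category`, joined by `tumor_id` when `calls`
#'   lacks a `category` column.
#' @return Tibble of class `architecture_table` with columns `category`,
#'   `n`, one count and one integer-percentage column per phenotype, and a
#'   final `"Total"` row. Raw fractions are kept in `frac_*` columns.
#' @export
tabulate_architecture <- function(calls, tumors = NULL) {
  calls <- as_tibble(calls)
  if (!"category" %in% names(calls)) {
    if (is.null(tumors)) {
      stop_param("`calls` lacks a category column and no `tumors` supplied.")
    }
    meta <- if (is.data.frame(tumors)) {
      as_tibble(tumors)[, c("tumor_id", "category")]
    } else {
      purrr::map_dfr(tumors, function(t)
        tibble(tumor_id = t$tumor_id, category = t$category))
    }
    calls <- dplyr::left_join(calls, meta, by = "tumor_id")
  }
  if (nrow(calls) > 0) {
    bad <- which(!calls$category %in% PATH_CATEGORIES)
    if (length(bad) > 0) {
      stop_param(sprintf("unknown category '%s' (row %d).",
                         calls$category[bad[1]], bad[1]), field = "category")
    }
    if (!all(calls$phenotype %in% PHENOTYPES)) {
      stop_param("phenotypes must be heterotypic/homotypic_red/homotypic_green.")
    }
  }

  counts_for <- function(df, label) {
    n <- nrow(df)
    cnt <- unname(vapply(PHENOTYPES, function(ph) sum(df$phenotype == ph),
                         integer(1)))
    frac <- if (n > 0) cnt / n else rep(0, 3)
    tibble(
      category = label, n = n,
      heterotypic = cnt[1], homotypic_red = cnt[2], homotypic_green = cnt[3],
      pct_heterotypic = round(100 * frac[1]),
      pct_homotypic_red = round(100 * frac[2]),
      pct_homotypic_green = round(100 * frac[3]),
      frac_heterotypic = frac[1], frac_homotypic_red = frac[2],
      frac_homotypic_green = frac[3])
  }
  present <- PATH_CATEGORIES[PATH_CATEGORIES %in% calls$category]
  rows <- purrr::map_dfr(present, function(cat)
    counts_for(calls[calls$category == cat, ], cat))
  out <- dplyr::bind_rows(rows, counts_for(calls, "Total"))
  class(out) <- c("architecture_table", class(out))
  out
}

#' Fraction of invasive tumors with simultaneous two-lineage invasion
#'
#' Among invasive adenocarcinomas with annotated invading lineages, the
#' fraction where both the red and the green lineage invade.
#'
#' @param tumors List of [tumor_region()] objects or a tibble with
#'   `category` and an `invading_lineages` list-column (or `"RED;GREEN"`
#'   style strings).
#' @return One-row tibble: `n_invasive`, `n_simultaneous`, `fraction`,
#'   `percent` (integer-rounded). With no invasive tumors the fraction is
#'   `NA`, `flagged = TRUE` and a warning is raised.
#' @export
simultaneous_invasion_rate <- function(tumors) {
  if (is.data.frame(tumors)) {
    cats <- tumors$category
    invading <- tumors$invading_lineages
  } else {
    cats <- purrr::map_chr(tumors, "category")
    invading <- purrr::map(tumors, "invading_lineages")
  }
  keep <- which(cats == "invasive")
  if (length(keep) == 0) {
    warn("No invasive tumors supplied; invasion rate undefined.")
    return(tibble(n_invasive = 0L, n_simultaneous = 0L,
                  fraction = NA_real_, percent = NA_real_, flagged = TRUE))
  }
  both <- vapply(invading[keep], function(v) {
    if (is.character(v) && length(v) == 1 && grepl("[;|]", v)) {
      v <- strsplit(v, "[;|]")[[1]]
    }
    all(c("RED", "GREEN") %in% v)
  }, logical(1))
  tibble(
    n_invasive = length(keep), n_simultaneous = sum(both),
    fraction = mean(both), percent = round(100 * mean(both)),
    flagged = FALSE)
}
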