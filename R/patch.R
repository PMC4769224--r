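#' Euclidean distance map to the nearest opposite lineage
#'
#' For every tissue pixel, the Euclidean distance (micrometres, between
#' pixel centres) to the nearest tissue pixel of the opposite lineage.
#' Non-tissue pixels carry `NA` and are neither sources nor targets: they
#' are transparent, not barriers, so the statistic is a pure property of
#' the red/green mosaic.
#'
#' @param labels A [label_map()].
#' @return Numeric matrix of distances in micrometres (`NA` outside
#'   tissue). If the map contains only one lineage the distances are
#'   `Inf` and the result carries attribute `degenerate = TRUE`: the
#'   patch size is unreportable.
#' @export
#' @examples
#' lm <- label_map(matrix(rep(1:2, length.out = 16), 4, 4), pixel_size = 1)
#' distance_map(lm)
distance_map <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  red <- lab == LBL_RED
  green <- lab == LBL_GREEN
  tissue <- red | green
  out <- matrix(NA_real_, nrow(lab), ncol(lab))
  if (!any(red) || !any(green)) {
    out[tissue] <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # distmap(x) gives each non-zero pixel's distance to the nearest zero
  # pixel, so 1 - mask places the targets at zero
  d_to_green <- EBImage::imageData(
    EBImage::distmap(matrix(as.numeric(!green), nrow(lab), ncol(lab))))
  d_to_red <- EBImage::imageData(
    EBImage::distmap(matrix(as.numeric(!red), nrow(lab), ncol(lab))))
  out[red] <- d_to_green[red]
  out[green] <- d_to_red[green]
  out * labels$pixel_size
}

#' Mosaic patch-size statistic
#'
#' The mosaic patch size is the mean over all tissue pixels of the
#' Euclidean distance to the nearest opposite-lineage pixel
#' ([distance_map()]); smaller values mean finer red/green interleaving
#' and hence better detection of multi-ancestral tumors. Per-lineage mean
#' distances are also reported, since the two lineages' patch sizes differ
#' when the green fraction is away from one half.
#'
#' @param labels A [label_map()].
#' @return One-row tibble with columns `n_tissue_pixels`,
#'   `green_fraction`, `mean_distance_um`, `red_mean_um`, `green_mean_um`.
#'   For a single-lineage map the distance columns are `NA` and the
#'   attribute `degenerate` is `TRUE`.
#' @export
patch_size <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  red <- lab == LBL_RED
  green <- lab == LBL_GREEN
  n_tissue <- sum(red) + sum(green)
  gf <- if (n_tissue > 0) sum(green) / n_tissue else NA_real_

  if (!any(red) || !any(green)) {
    out <- tibble(n_tissue_pixels = n_tissue, green_fraction = gf,
                  mean_distance_um = NA_real_, red_mean_um = NA_real_,
                  green_mean_um = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- distance_map(labels)
  tibble(
    n_tissue_pixels = n_tissue,
    green_fraction = gf,
    mean_distance_um = mean(d[red | green]),
    red_mean_um = mean(d[red]),
    green_mean_um = mean(d[green])
  )
}

#' Patch statistics per intestinal tract section
#'
#' Pools label maps by tract section and reports one patch-statistics row
#' per section, plus a pooled distal summary (section 4 and the colon),
#' mirroring the practice of plotting the ileum and colon separately from
#' the nearly all-red proximal sections. Pooling is over all tissue
#' pixels of the section's maps; per-map averaging is available via
#' `pool = "per_map"`.
#'
#' @param maps A tibble (or data frame) with a list-column `label_map` of
#'   [label_map()] objects and an integer column `tract_section`, or a
#'   plain list of label maps accompanied by `tract_section`.
#' @param tract_section Integer vector of sections, used when `maps` is a
#'   plain list.
#' @param pool `"pixels"` (default) pools all tissue pixels per section;
#'   `"per_map"` averages per-map statistics.
#' @return Tibble with one row per observed section (column
#'   `tract_section`, `"distal"` for the pooled section-4 + colon row) and
#'   the [patch_size()] columns. Sections with only one lineage present
#'   have `NA` distances.
#' @export
section_profile <- function(maps, tract_section = NULL,
                            pool = c("pixels", "per_map")) {
  pool <- match.arg(pool)
  if (is.data.frame(maps)) {
    stopifnot(all(c("label_map", "tract_section") %in% names(maps)))
    lms <- maps$label_map
    secs <- maps$tract_section
  } else {
    lms <- maps
    secs <- tract_section
    stopifnot(length(lms) == length(secs))
  }
  if (length(lms) == 0) stop_param("at least one label map is required.")

  one_group <- function(idx, label) {
    if (pool == "per_map") {
      stats <- purrr::map(lms[idx], patch_size)
      row <- purrr::map_dfr(stats, identity) |>
        dplyr::summarise(
          n_tissue_pixels = sum(.data$n_tissue_pixels),
          green_fraction = mean(.data$green_fraction),
          mean_distance_um = mean(.data$mean_distance_um),
          red_mean_um = mean(.data$red_mean_um),
          green_mean_um = mean(.data$green_mean_um))
    } else {
      # pixel pooling: concatenate per-pixel distances across maps
      acc <- purrr::map(lms[idx], function(lm) {
        lab <- lm$labels
        red <- lab == LBL_RED; green <- lab == LBL_GREEN
        if (!any(red) || !any(green)) {
          return(list(n = sum(red) + sum(green), g = sum(green),
                      d_red = numeric(0), d_green = numeric(0),
                      degenerate = sum(red) + sum(green) > 0))
        }
        d <- distance_map(lm)
        list(n = sum(red) + sum(green), g = sum(green),
             d_red = d[red], d_green = d[green], degenerate = FALSE)
      })
      n <- sum(purrr::map_dbl(acc, "n"))
      g <- sum(purrr::map_dbl(acc, "g"))
      d_red <- unlist(purrr::map(acc, "d_red"))
      d_green <- unlist(purrr::map(acc, "d_green"))
      degenerate <- any(purrr::map_lgl(acc, "degenerate")) &&
        length(d_red) + length(d_green) == 0
      row <- tibble(
        n_tissue_pixels = n,
        green_fraction = if (n > 0) g / n else NA_real_,
        mean_distance_um = if (degenerate) NA_real_
          else mean(c(d_red, d_green)),
        red_mean_um = if (degenerate) NA_real_ else mean(d_red),
        green_mean_um = if (degenerate) NA_real_ else mean(d_green))
    }
    dplyr::mutate(row, tract_section = label, .before = 1)
  }

  secs_chr <- as.character(secs)
  out <- purrr::map_dfr(sort(unique(secs_chr)),
                        function(s) one_group(which(secs_chr == s), s))
  distal <- which(secs %in% c(4L, 5L))
  if (length(distal) > 0) {
    out <- dplyr::bind_rows(out, one_group(distal, "distal"))
  }
  out
}
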