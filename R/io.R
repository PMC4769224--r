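#' Write and read two-channel whole mounts as TIFF
#'
#' The two channels are written as a two-plane 16-bit TIFF; the physical
#' pixel size and channel names go into a JSON sidecar (`<path>.json`)
#' because plain TIFF carries no calibrated pixel size.
#'
#' @param image A `whole_mount_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_whole_mount <- function(image, path) {
  stopifnot(inherits(image, "whole_mount_image"))
  clip <- function(m) t(pmin(pmax(m, 0), 1))
  tiff::writeTIFF(list(clip(image$red), clip(image$green)), path,
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size,
         channels = c("red_tdTomato", "green_EGFP"),
         writer = paste0("clonalmosaic ", as.character(packageVersion("clonalmosaic")))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_whole_mount
#' @param pixel_size Pixel size override when no sidecar is present.
#' @export
read_whole_mount <- function(path, pixel_size = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 2) {
    stop_param(sprintf("expected a 2-plane TIFF, found %d plane(s).",
                       length(planes)))
  }
  sidecar <- paste0(path, ".json")
  if (is.null(pixel_size)) {
    if (!file.exists(sidecar)) {
      stop_param("no pixel size: supply `pixel_size` or a JSON sidecar.")
    }
    pixel_size <- jsonlite::read_json(sidecar)$pixel_size_um
  }
  structure(
    list(red = t(planes[[1]]), green = t(planes[[2]]),
         pixel_size = pixel_size, truth = NULL, tumor_id = NULL),
    class = "whole_mount_image")
}

#' Write and read label maps as single-channel TIFF
#'
#' Pixel values 0 (non-tissue), 1 (red), 2 (green) stored in an 8-bit
#' plane; pixel size in a JSON sidecar.
#'
#' @param labels A [label_map()].
#' @param path Output TIFF path.
#' @return `path` invisibly; `read_label_map()` returns a [label_map()].
#' @export
write_label_map <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  tiff::writeTIFF(t(labels$labels) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = labels$pixel_size,
         palette = list(`0` = "NON_TISSUE", `1` = "RED", `2` = "GREEN")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @param pixel_size Pixel size override when no sidecar is present.
#' @export
read_label_map <- function(path, pixel_size = NULL) {
  m <- tiff::readTIFF(path)
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop_param("no pixel size: supply `pixel_size` or a JSON sidecar.")
    }
    pixel_size <- jsonlite::read_json(sidecar)$pixel_size_um
  }
  label_map(t(round(m * 255)), pixel_size)
}

#' Read per-tumor annotations from CSV
#'
#' Expects columns `tumor_id`, `category`, `tract_section`,
#' `invading_lineages` (`;`-separated, may be empty). Unknown categories,
#' duplicate ids and missing columns are parse errors reporting the
#' offending row.
#'
#' @param path CSV path.
#' @return Tibble with one row per tumor; `invading_lineages` is a
#'   list-column of character vectors.
#' @export
read_tumor_annotations <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"))
  required <- c("tumor_id", "category", "tract_section", "invading_lineages")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_param(sprintf("missing required column(s): %s.",
                       paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(tibble(tumor_id = character(), category = character(),
                  tract_section = integer(),
                  invading_lineages = list()))
  }
  dup <- which(duplicated(df$tumor_id))
  if (length(dup) > 0) {
    stop_param(sprintf("duplicate tumor_id '%s' (row %d).",
                       df$tumor_id[dup[1]], dup[1]))
  }
  bad <- which(!df$category %in% PATH_CATEGORIES)
  if (length(bad) > 0) {
    stop_param(sprintf("unknown category '%s' (row %d); expected one of %s.",
                       df$category[bad[1]], bad[1],
                       paste(PATH_CATEGORIES, collapse = ", ")))
  }
  sect <- suppressWarnings(as.integer(df$tract_section))
  bad_s <- which(is.na(sect) | !sect %in% 1:5)
  if (length(bad_s) > 0) {
    stop_param(sprintf("invalid tract_section '%s' (row %d).",
                       df$tract_section[bad_s[1]], bad_s[1]))
  }
  inv <- purrr::map(df$invading_lineages, function(s) {
    if (is.na(s) || s == "") return(character())
    v <- strsplit(s, "[;|]")[[1]]
    if (!all(v %in% c("RED", "GREEN"))) {
      stop_param(sprintf("invalid invading_lineages '%s'.", s))
    }
    v
  })
  tibble(tumor_id = df$tumor_id, category = df$category,
         tract_section = sect, invading_lineages = inv)
}

#' Write and read per-tumor clonality calls as CSV
#'
#' Lossless round-trip of [classify_tumor()] call tables.
#'
#' @param calls Tibble of calls.
#' @param path CSV path.
#' @return `path` invisibly; `read_calls()` returns the tibble.
#' @export
write_calls <- function(calls, path) {
  write.csv(as.data.frame(calls), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("tumor_id", "phenotype") %in% names(df))) {
    stop_param("calls CSV must contain tumor_id and phenotype columns.")
  }
  df$tumor_id <- as.character(df$tumor_id)
  df
}

#' Write an architecture table as CSV
#'
#' @param table An [tabulate_architecture()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
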