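#' Parameters for a synthetic mosaic crypt lattice
#'
#' Bundles the parameters that define one tract section of a synthetic
#' mosaic intestine: the expected green (EGFP, Cre-positive) lineage
#' fraction `p`, the spatial correlation length controlling mosaic patch
#' size, the number of crypts, and the crypt radius.
#'
#' @param p Expected green lineage fraction, in `[0, 1]`. The default is
#'   the measured colon value for 150-day-old mosaic mice (37.6%).
#' @param correlation_length Length scale (micrometres) of the Gaussian
#'   smoothing kernel applied to per-crypt white noise before thresholding;
#'   larger values give larger same-lineage patches. `0` gives independent
#'   per-crypt lineages.
#' @param n_crypts Number of crypts to place.
#' @param crypt_radius Crypt radius in micrometres.
#' @param seed Integer seed for the lattice's random number stream.
#'
#' @return A list of class `mosaic_params`.
#' @export
#' @examples
#' mosaic_params(p = 0.12, n_crypts = 500)
mosaic_params <- function(p = 0.376, correlation_length = 100,
                          n_crypts = 5000, crypt_radius = 25, seed = 1L) {
  check_fraction(p, "p")
  check_positive(correlation_length, "correlation_length", strict = FALSE)
  if (!is.numeric(n_crypts) || length(n_crypts) != 1 || n_crypts < 1 ||
      n_crypts != round(n_crypts)) {
    stop_param("`n_crypts` must be a positive integer.", field = "n_crypts")
  }
  check_positive(crypt_radius, "crypt_radius")
  structure(
    list(p = p, correlation_length = correlation_length,
         n_crypts = as.integer(n_crypts), crypt_radius = crypt_radius,
         seed = as.integer(seed)),
    class = "mosaic_params"
  )
}

#' Green-fraction presets along the intestinal tract
#'
#' Green lineage fractions per tract section for the Fabp1-Cre gradient:
#' the proximal small intestine (sections 1-3) is almost entirely red,
#' section 4 (ileum) is 12% green and the colon (section 5) 37.6% green.
#'
#' @return A tibble with columns `tract_section` (1-5) and `p`.
#' @export
tract_gradient_preset <- function() {
  tibble(tract_section = 1:5, p = c(0, 0.01, 0.02, 0.12, 0.376))
}

#' Generate a synthetic crypt lattice with mosaic lineage labels
#'
#' Places crypts on a jittered hexagonal packing and assigns each crypt a
#' lineage (`"RED"` or `"GREEN"`) by thresholding a spatially correlated
#' Gaussian random field at the quantile giving expected green fraction
#' `p`. The field is white noise on crypt centres smoothed with a Gaussian
#' kernel whose bandwidth is `correlation_length`, renormalised so each
#' crypt's field value is marginally standard normal; the empirical green
#' fraction therefore converges to `p` as the number of crypts grows, and
#' patch size grows with `correlation_length`.
#'
#' @param params A [mosaic_params()] object.
#' @param tract_section Integer 1-5 recorded on every crypt (1-4 = small
#'   intestine quarters, 5 = colon).
#'
#' @return A tibble of class `crypt_lattice` with columns `crypt_id`, `x`,
#'   `y` (micrometres), `lineage`, `tract_section`, and attributes
#'   `crypt_radius`, `spacing`, `params`.
#' @export
#' @examples
#' lat <- generate_lattice(mosaic_params(p = 0.376, n_crypts = 400, seed = 7))
#' mean(lat$lineage == "GREEN")
generate_lattice <- function(params, tract_section = 5L) {
  stopifnot(inherits(params, "mosaic_params"))
  if (!tract_section %in% 1:5) {
    stop_param("`tract_section` must be an integer in 1..5.",
               field = "tract_section")
  }
  n <- params$n_crypts
  r <- params$crypt_radius
  ell <- params$correlation_length

  # hexagonal packing at spacing 2.4 r with a small positional jitter;
  # jitter is bounded so centres stay >= one crypt diameter apart
  spacing <- 2.4 * r
  ncol_grid <- ceiling(sqrt(n * 2 / sqrt(3)))
  nrow_grid <- ceiling(n / ncol_grid)
  ij <- expand.grid(col = seq_len(ncol_grid), row = seq_len(nrow_grid))
  ij <- ij[seq_len(n), , drop = FALSE]

  rng <- local({
    set.seed(params$seed)
    list(jx = runif(n, -0.1 * r, 0.1 * r),
         jy = runif(n, -0.1 * r, 0.1 * r),
         eps = rnorm(n))
  })

  x <- (ij$col - 1) * spacing + ifelse(ij$row %% 2 == 0, spacing / 2, 0) +
    rng$jx + spacing
  y <- (ij$row - 1) * spacing * sqrt(3) / 2 + rng$jy + spacing

  z <- smooth_field(x, y, rng$eps, ell)
  lineage <- ifelse(z < qnorm(params$p), "GREEN", "RED")

  out <- tibble(
    crypt_id = seq_len(n), x = x, y = y,
    lineage = lineage, tract_section = as.integer(tract_section)
  )
  class(out) <- c("crypt_lattice", class(out))
  attr(out, "crypt_radius") <- r
  attr(out, "spacing") <- spacing
  attr(out, "params") <- params
  out
}

# Gaussian-kernel smoothing of white noise on scattered points, computed in
# row blocks to bound memory at O(block * n). The output is renormalised so
# each value is marginally N(0, 1) whatever the kernel bandwidth.
smooth_field <- function(x, y, eps, ell) {
  n <- length(x)
  if (ell <= 0 || n == 1) return(eps)
  z <- numeric(n)
  block <- max(1L, min(n, as.integer(2e6 / n) + 1L))
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    w <- exp(-d2 / (2 * ell^2))
    z[idx] <- as.vector(w %*% eps) / sqrt(rowSums(w^2))
  }
  z
}

#' Seed a synthetic tumor from one or more founder crypts
#'
#' The first founder is drawn uniformly over the lattice; the remaining
#' `founder_count - 1` founders are drawn without replacement from crypts
#' within `recruitment_radius` of the first, reflecting a primogenitor
#' recruiting nearby co-genitors. The tumor region is the union of discs of
#' radius `recruitment_radius` around the founders, which is contiguous by
#' construction.
#'
#' @param lattice A [generate_lattice()] result.
#' @param founder_count Number of founder crypts (>= 1).
#' @param recruitment_radius Radius (micrometres) within which co-founders
#'   are recruited; also sets the rendered tumor blob size.
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_tumor` with elements
#'   `founder_crypts`, `founder_count`, `founder_lineages`,
#'   `heterotypic_truth`, `recruitment_radius`, and founder coordinates.
#' @export
seed_tumor <- function(lattice, founder_count, recruitment_radius = 150,
                       seed = 1L) {
  stopifnot(inherits(lattice, "crypt_lattice"))
  if (nrow(lattice) == 0) stop_param("`lattice` must contain crypts.")
  if (founder_count < 1 || founder_count != round(founder_count)) {
    stop_param("`founder_count` must be a positive integer.",
               field = "founder_count")
  }
  check_positive(recruitment_radius, "recruitment_radius")

  set.seed(seed)
  first <- sample.int(nrow(lattice), 1L)
  founders <- first
  if (founder_count > 1) {
    d <- sqrt((lattice$x - lattice$x[first])^2 +
              (lattice$y - lattice$y[first])^2)
    pool <- setdiff(which(d <= recruitment_radius), first)
    if (length(pool) < founder_count - 1) {
      abort(sprintf(
        "Only %d crypts within %.0f um of the first founder; %d needed.",
        length(pool), recruitment_radius, founder_count - 1),
        class = "clonalmosaic_geometry_error")
    }
    founders <- c(first, sample(pool, founder_count - 1L))
  }

  lineages <- lattice$lineage[founders]
  structure(
    list(
      founder_crypts = founders,
      founder_count = as.integer(founder_count),
      founder_lineages = lineages,
      heterotypic_truth = length(unique(lineages)) == 2L,
      recruitment_radius = recruitment_radius,
      founder_x = lattice$x[founders],
      founder_y = lattice$y[founders]
    ),
    class = "synthetic_tumor"
  )
}

#' @export
print.synthetic_tumor <- function(x, ...) {
  cat(sprintf("<synthetic_tumor> %d founder(s): %s (%s)\n",
              x$founder_count, paste(x$founder_lineages, collapse = ", "),
              if (x$heterotypic_truth) "heterotypic" else "homotypic"))
  invisible(x)
}

#' Render a two-channel fluorescence whole mount from a crypt lattice
#'
#' Forward model for whole-mount imaging: crypt territories (Voronoi cells
#' of crypt centres, limited to a tissue band around the lattice) are
#' painted bright in the channel of their lineage; tumor regions are
#' painted by the Voronoi cell of their nearest founder, so multi-founder
#' tumors show discrete clone territories. A smooth multiplicative
#' illumination gradient and additive Gaussian noise are applied, and the
#' background (non-tissue) is near zero in both channels.
#'
#' @param lattice A [generate_lattice()] result (may have zero rows).
#' @param tumors List of [seed_tumor()] results.
#' @param noise_sd Standard deviation of additive Gaussian noise, on the
#'   `[0, 1]` intensity scale.
#' @param illumination_gradient Peak-to-centre relative amplitude of a
#'   linear illumination field across the image width.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed for the noise.
#' @param foreground,background Mean intensities of lineage-positive and
#'   non-tissue pixels.
#'
#' @return A list of class `whole_mount_image` with elements `red`,
#'   `green` (matrices indexed `[x, y]`), `pixel_size`, `truth` (the true
#'   [label_map()]), and `tumor_id` (integer matrix, 0 = no tumor).
#' @export
render_whole_mount <- function(lattice, tumors = list(), noise_sd = 0.08,
                               illumination_gradient = 0.2, pixel_size = 5,
                               seed = 1L, foreground = 0.85,
                               background = 0.03) {
  check_positive(pixel_size, "pixel_size")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(illumination_gradient, "illumination_gradient",
                 strict = FALSE)

  if (nrow(lattice) == 0) {
    dims <- c(64L, 64L)
    labels <- matrix(LBL_NON_TISSUE, dims[1], dims[2])
    tumor_id <- matrix(0L, dims[1], dims[2])
  } else {
    spacing <- attr(lattice, "spacing") %||% (2.4 * 25)
    margin <- 1.2 * spacing
    x0 <- min(lattice$x) - margin
    y0 <- min(lattice$y) - margin
    nx <- as.integer(ceiling((max(lattice$x) + margin - x0) / pixel_size))
    ny <- as.integer(ceiling((max(lattice$y) + margin - y0) / pixel_size))

    cx <- pmin(pmax(as.integer(ceiling((lattice$x - x0) / pixel_size)), 1L), nx)
    cy <- pmin(pmax(as.integer(ceiling((lattice$y - y0) / pixel_size)), 1L), ny)
    seeds <- matrix(0L, nx, ny)
    seeds[cbind(cx, cy)] <- lattice$crypt_id

    # distance of every pixel to the nearest crypt centre defines the
    # tissue band; Voronoi propagation assigns each tissue pixel a crypt
    dist_to_centre <- EBImage::imageData(
      EBImage::distmap(matrix(as.numeric(seeds == 0L), nx, ny))) * pixel_size
    tissue <- dist_to_centre <= 0.7 * spacing
    vor <- EBImage::imageData(EBImage::propagate(
      EBImage::Image(matrix(0, nx, ny)), seeds, mask = tissue, lambda = 1e8))
    vor <- matrix(as.integer(vor), nx, ny)

    labels <- matrix(LBL_NON_TISSUE, nx, ny)
    in_tissue <- tissue & vor > 0L
    labels[in_tissue] <-
      ifelse(lattice$lineage[vor[in_tissue]] == "GREEN", LBL_GREEN, LBL_RED)

    # paint tumors: within each blob, pixels take the lineage of the
    # nearest founder crypt, giving contiguous per-founder clone territories
    tumor_id <- matrix(0L, nx, ny)
    px <- ((seq_len(nx)) - 0.5) * pixel_size + x0
    py <- ((seq_len(ny)) - 0.5) * pixel_size + y0
    for (k in seq_along(tumors)) {
      tum <- tumors[[k]]
      stopifnot(inherits(tum, "synthetic_tumor"))
      dmin <- NULL
      lab_near <- NULL
      for (j in seq_along(tum$founder_x)) {
        d2 <- outer(px - tum$founder_x[j], py - tum$founder_y[j],
                    function(a, b) a^2 + b^2)
        if (is.null(dmin)) {
          dmin <- d2
          lab_near <- matrix(tum$founder_lineages[j], nx, ny)
        } else {
          closer <- d2 < dmin
          dmin[closer] <- d2[closer]
          lab_near[closer] <- tum$founder_lineages[j]
        }
      }
      blob <- dmin <= tum$recruitment_radius^2
      blob <- blob & labels != LBL_NON_TISSUE
      labels[blob] <- ifelse(lab_near[blob] == "GREEN", LBL_GREEN, LBL_RED)
      tumor_id[blob] <- k
    }
  }

  nx <- nrow(labels); ny <- ncol(labels)
  red <- matrix(background, nx, ny)
  green <- matrix(background, nx, ny)
  red[labels == LBL_RED] <- foreground
  green[labels == LBL_GREEN] <- foreground

  illum <- 1 + illumination_gradient *
    (matrix(seq_len(nx) / nx, nx, ny) - 0.5)
  set.seed(seed)
  red <- pmax(red * illum + rnorm(nx * ny, sd = noise_sd), 0)
  green <- pmax(green * illum + rnorm(nx * ny, sd = noise_sd), 0)

  structure(
    list(red = red, green = green, pixel_size = pixel_size,
         truth = label_map(labels, pixel_size), tumor_id = tumor_id),
    class = "whole_mount_image"
  )
}

#' @export
print.whole_mount_image <- function(x, ...) {
  cat(sprintf("<whole_mount_image> %d x %d px, %.3g um/px\n",
              nrow(x$red), ncol(x$red), x$pixel_size))
  invisible(x)
}
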