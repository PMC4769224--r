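#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a multi-ancestral fraction estimate
#'
#' @param x A [estimate_multiancestral_fraction()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.multiancestral_estimate <- function(x, ...) {
  tibble(term = "multiancestral_fraction", estimate = x$f_hat,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.multiancestral_estimate
#' @return `glance()`: one-row tibble with the model inputs `x_het`, `n`,
#'   `p`, `N`, the detection probability `h`, and the method.
#' @export
glance.multiancestral_estimate <- function(x, ...) {
  tibble(x_het = x$x_het, n = x$n, p = x$p, N = x$N, h = x$h,
         conf.level = x$conf_level, method = x$method)
}

#' Tidy an architecture table into long counts
#'
#' @param x An [tabulate_architecture()] result.
#' @param ... Unused.
#' @return Long tibble: `category`, `phenotype`, `count`, `percent`.
#' @export
tidy.architecture_table <- function(x, ...) {
  as_tibble(x) |>
    dplyr::select("category", "n", dplyr::all_of(PHENOTYPES)) |>
    tidyr::pivot_longer(dplyr::all_of(PHENOTYPES),
                        names_to = "phenotype", values_to = "count") |>
    dplyr::mutate(percent = round(100 * .data$count / pmax(.data$n, 1)))
}

#' Summarise a crypt lattice
#'
#' @param x A [generate_lattice()] result.
#' @param ... Unused.
#' @return One-row tibble: `n_crypts`, `green_fraction`, `p`,
#'   `correlation_length`, `crypt_radius`.
#' @export
glance.crypt_lattice <- function(x, ...) {
  params <- attr(x, "params")
  tibble(n_crypts = nrow(x), green_fraction = mean(x$lineage == "GREEN"),
         p = params$p, correlation_length = params$correlation_length,
         crypt_radius = params$crypt_radius)
}
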