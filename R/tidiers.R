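# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a filtering funnel into one row per stage
#'
#' @param x A `ps_cascade`.
#' @param ... Unused.
#' @return Tibble with `stage`, `label`, `n`.
#' @export
tidy.ps_cascade <- function(x, ...) x$stages

#' One-row summary of a filtering funnel
#'
#' @param x A `ps_cascade`.
#' @param ... Unused.
#' @return One-row tibble with the six stage counts as columns.
#' @export
glance.ps_cascade <- function(x, ...) {
  tibble::as_tibble(as.list(setNames(x$stages$n, x$stages$stage)))
}

#' Tidy a cohort deletion screen into its calls
#'
#' @param x A `ps_cnv_screen`.
#' @param ... Unused.
#' @return The deletion-call tibble (one row per call).
#' @export
tidy.ps_cnv_screen <- function(x, ...) x$calls

#' One-row summary of a cohort deletion screen
#'
#' @param x A `ps_cnv_screen`.
#' @param ... Unused.
#' @return One-row tibble: samples, windows, total calls and calls by class.
#' @export
glance.ps_cnv_screen <- function(x, ...) {
  tibble::tibble(
    n_samples = length(unique(x$counts$sample_id)),
    n_windows = nrow(x$windows),
    n_calls = nrow(x$calls),
    n_het = sum(x$calls$zygosity_class == "het"),
    n_hom = sum(x$calls$zygosity_class == "hom"),
    n_mosaic = sum(x$calls$zygosity_class == "mosaic")
  )
}
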