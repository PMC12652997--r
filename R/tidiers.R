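# broom-style tidiers.

#' Tidy a call set into long per-sample form
#'
#' @param x A [call_set()].
#' @param ... Unused.
#' @return A tibble with one row per record x sample: the allele key,
#'   variant class, sample, GT string and genotype class.
#' @method tidy call_set
#' @export
tidy.call_set <- function(x, ...) {
  samples <- call_set_samples(x)
  base <- key_cols(x)
  base$variant_class <- classify_allele(x$ref, x$alt)
  purrr::map_dfr(samples, function(s) {
    out <- base
    out$sample <- s
    out$gt <- x[[paste0("gt_", s)]]
    out$genotype_class <- genotype_class(out$gt)
    out
  })
}

#' One-row summary of a call set
#'
#' @param x A [call_set()].
#' @param ... Unused.
#' @return [callset_summary()] of the call set.
#' @method glance call_set
#' @export
glance.call_set <- function(x, ...) {
  callset_summary(x)
}

#' @method tidy spectrum_result
#' @export
tidy.spectrum_result <- function(x, ...) {
  out <- as_tibble(x)
  out$sample <- attr(x, "sample")
  out
}

#' @method tidy spectrum_contrast
#' @export
tidy.spectrum_contrast <- function(x, ...) {
  as_tibble(x)
}

#' Tidy tier counts of a prioritization report
#'
#' @param x A `prioritization_report`.
#' @param ... Unused.
#' @return The long tier x sample count tibble.
#' @method tidy prioritization_report
#' @export
tidy.prioritization_report <- function(x, ...) {
  x$counts
}

#' Final-tier summary of a prioritization report
#'
#' @param x A `prioritization_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of cases and the shared surviving
#'   candidate count at each tier.
#' @method glance prioritization_report
#' @export
glance.prioritization_report <- function(x, ...) {
  shared <- x$counts[x$counts$sample == "shared", ]
  out <- as_tibble(setNames(as.list(shared$n), as.character(shared$tier)))
  mutate(out, n_cases = length(x$cases), .before = 1)
}
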