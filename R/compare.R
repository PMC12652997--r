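# Truth-set construction and sample-wise benchmarking. All set operations
# are over trimmed allele keys (contig, pos, ref, alt), approximating the
# allele matching of `bcftools isec` on normalized call sets. A sample's
# variant set contains the keys at which its genotype class is het or
# hom_alt; hom-ref and missing genotypes are excluded on both sides.

#' Partition two call sets into shared and unique records
#'
#' The allele-key union of two normalized call sets is partitioned by
#' membership. The shared partition carries genotypes and annotations from
#' `a` (the designated primary caller); typical use takes `a` and `b` as
#' the outputs of two callers on the same samples and uses the shared
#' partition as a truth set.
#'
#' @param a,b Call sets normalized by the same pipeline ([read_vcf()] or a
#'   simulator).
#' @param variant_class Optional class filter applied to both inputs first:
#'   `"snv"`, `"indel"` (insertions + deletions), `"insertion"`,
#'   `"deletion"` or `"mnv"`.
#' @return A list with call sets `shared`, `unique_a` and `unique_b`.
#' @export
intersect_callsets <- function(a, b, variant_class = NULL) {
  a <- call_set(a, attr(a, "provenance"))
  b <- call_set(b, attr(b, "provenance"))
  if (!is.null(variant_class)) {
    a <- cs_filter(a, variant_class_match(a, variant_class))
    b <- cs_filter(b, variant_class_match(b, variant_class))
  }
  if (length(intersect(call_set_samples(a), call_set_samples(b))) == 0 &&
      length(call_set_samples(a)) > 0 && length(call_set_samples(b)) > 0) {
    warn("Call sets share no sample names; site-level sharing only.")
  }
  if (nrow(a) > 0 && nrow(b) > 0 &&
      length(intersect(unique(a$contig), unique(b$contig))) == 0) {
    warn(paste("Call sets share no contig names;",
               "check for chr-prefix mismatches."))
  }
  ka <- variant_key(a)
  kb <- variant_key(b)
  in_b <- ka %in% kb
  list(
    shared = cs_filter(a, in_b),
    unique_a = cs_filter(a, !in_b),
    unique_b = cs_filter(b, !(kb %in% ka))
  )
}

variant_class_match <- function(cs, variant_class) {
  variant_class <- match.arg(
    variant_class, c("snv", "indel", "insertion", "deletion", "mnv")
  )
  cls <- classify_allele(cs$ref, cs$alt)
  if (variant_class == "indel") {
    cls %in% c("insertion", "deletion")
  } else {
    cls == variant_class
  }
}

#' Compare one sample's calls between a truth and a query call set
#'
#' The per-sample variant set on each side contains the allele keys at
#' which the sample's genotype class is het or hom_alt (hom-ref and missing
#' calls are excluded from both totals). True positives are keys present in
#' both sets, false negatives keys only in truth, false positives keys only
#' in the query; `concordant` counts true-positive keys whose unordered
#' genotype classes agree exactly.
#'
#' @param truth,query Call sets containing `sample`.
#' @param sample Sample name.
#' @return A one-row tibble with columns `sample`, `truth_total`,
#'   `query_total`, `tp`, `fp`, `fn`, `concordant`.
#' @export
compare_sample <- function(truth, query, sample) {
  tr <- sample_variant_records(truth, sample)
  qr <- sample_variant_records(query, sample)
  tk <- variant_key(tr)
  qk <- variant_key(qr)
  hit <- match(tk, qk)
  tp <- sum(!is.na(hit))
  t_cls <- genotype_class(tr[[paste0("gt_", sample)]])
  q_cls <- genotype_class(qr[[paste0("gt_", sample)]])
  concordant <- sum(t_cls[!is.na(hit)] == q_cls[hit[!is.na(hit)]])
  tibble(
    sample = sample,
    truth_total = length(tk),
    query_total = length(qk),
    tp = tp,
    fp = length(qk) - tp,
    fn = length(tk) - tp,
    concordant = concordant
  )
}

#' Benchmark a query call set against a truth call set
#'
#' Convenience wrapper running [compare_sample()] and
#' [performance_metrics()] for each sample and variant class. SNVs and
#' indels are stratified before comparison; MNV records are reported as
#' their own stratum and excluded from both.
#'
#' @param truth,query Call sets.
#' @param samples Sample names (default: samples common to both call sets).
#' @param classes Variant-class strata to report.
#' @return A tibble with one row per sample and class: comparison counts
#'   plus derived metrics.
#' @export
compare_callsets <- function(truth, query,
                             samples = NULL,
                             classes = c("snv", "indel", "mnv")) {
  samples <- samples %||%
    intersect(call_set_samples(truth), call_set_samples(query))
  if (length(samples) == 0) {
    abort("No common samples between truth and query call sets.")
  }
  out <- purrr::map_dfr(classes, function(cl) {
    tr <- cs_filter(truth, variant_class_match(truth, cl))
    qr <- cs_filter(query, variant_class_match(query, cl))
    purrr::map_dfr(samples, function(s) compare_sample(tr, qr, s)) |>
      mutate(class = cl, .before = 1)
  })
  performance_metrics(out)
}

#' Derive benchmarking metrics from comparison counts
#'
#' Computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, their harmonic
#' mean F1, the false-negative rate `fn/truth_total`, the false-positive
#' rate `fp/(tp+fp)` (fraction of query positives) and genotype concordance
#' `concordant/tp` (fraction of recovered true positives). Ratios with a
#' zero denominator are `NA`, which is distinct from 0. All metrics are
#' fractions in \[0, 1\]; multiply by 100 for table-style percentages.
#'
#' The function is vectorized over rows, so a tibble of published counts
#' (e.g. [ffpe_study_counts()]) reproduces the corresponding published
#' percentages directly.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`; optional
#'   `truth_total` (default `tp + fn`) and `concordant`.
#' @return The input tibble with metric columns appended.
#' @export
#' @examples
#' performance_metrics(
#'   tibble::tibble(tp = 3985449, fp = 149890, fn = 165254)
#' )
performance_metrics <- function(counts) {
  x <- as_tibble(counts)
  for (col in c("tp", "fp", "fn")) {
    if (!col %in% names(x)) {
      abort(paste0("`counts` needs a `", col, "` column."))
    }
  }
  truth_total <- if ("truth_total" %in% names(x)) {
    ifelse(is.na(x$truth_total), x$tp + x$fn, x$truth_total)
  } else {
    x$tp + x$fn
  }
  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0,
                                        num / den, NA_real_)
  precision <- safe_div(x$tp, x$tp + x$fp)
  recall <- safe_div(x$tp, x$tp + x$fn)
  f1 <- ifelse(
    !is.na(precision) & !is.na(recall) & precision + recall > 0,
    2 * precision * recall / (precision + recall),
    NA_real_
  )
  x$precision <- precision
  x$recall <- recall
  x$f1 <- f1
  x$fn_rate <- safe_div(x$fn, truth_total)
  x$fp_rate <- safe_div(x$fp, x$tp + x$fp)
  x$genotype_concordance <- if ("concordant" %in% names(x)) {
    safe_div(x$concordant, x$tp)
  } else {
    NA_real_
  }
  x
}
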