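# Call-set characterization: Ts/Tv, het/hom, del/ins ratios, singleton and
# multiallelic-site counts, and per-sample substitution spectra with
# Poisson standard errors. Ratios with a zero denominator are NA rather
# than 0 or Inf.

#' Transition/transversion ratio of an SNV set
#'
#' Transitions are A<->G and C<->T; everything else is a transversion.
#' Genome-wide germline call sets in mammals sit around 2.0-2.1; values
#' near 1 indicate random-mismatch artifact enrichment (a random
#' substitution is a transition 1/3 of the time).
#'
#' @param x A call set or data frame with `ref`/`alt` columns; all records
#'   must be SNVs.
#' @return The ratio transitions/transversions (`NA` if no transversions).
#' @export
#' @examples
#' ts_tv_ratio(tibble::tibble(ref = c("A", "C", "A", "G"),
#'                            alt = c("G", "T", "C", "T")))
ts_tv_ratio <- function(x) {
  if (any(classify_allele(x$ref, x$alt) != "snv")) {
    abort("ts_tv_ratio() expects SNV records only.")
  }
  ts <- sum(is_transition(x$ref, x$alt))
  tv <- nrow(as_tibble(x)) - ts
  if (tv == 0) NA_real_ else ts / tv
}

#' Deletion/insertion ratio of an indel set
#'
#' @param x A call set or data frame with `ref`/`alt` columns; all records
#'   must be insertions or deletions.
#' @return Deletion count / insertion count (`NA` if no insertions).
#' @export
del_ins_ratio <- function(x) {
  cls <- classify_allele(x$ref, x$alt)
  if (any(!cls %in% c("insertion", "deletion"))) {
    abort("del_ins_ratio() expects insertion/deletion records only.")
  }
  n_ins <- sum(cls == "insertion")
  n_del <- sum(cls == "deletion")
  if (n_ins == 0) NA_real_ else n_del / n_ins
}

#' Heterozygous/homozygous-alternate ratio
#'
#' `het_hom_ratio()` computes one sample's het/hom-alt count ratio over its
#' non-reference, non-missing calls; `het_hom_table()` tabulates every
#' sample; `mean_het_hom()` is the arithmetic mean of the per-sample
#' ratios (the "averaged het/hom across samples" convention of call-set
#' summary tables).
#'
#' @param cs A call set.
#' @param sample Sample name.
#' @return A ratio (`NA` when the sample has no hom-alt calls), a tibble,
#'   or a mean ratio respectively.
#' @export
het_hom_ratio <- function(cs, sample) {
  if (!sample %in% call_set_samples(cs)) {
    abort(paste0("Sample `", sample, "` is not in the call set."))
  }
  cls <- genotype_class(cs[[paste0("gt_", sample)]])
  n_hom <- sum(cls == "hom_alt")
  if (n_hom == 0) NA_real_ else sum(cls == "het") / n_hom
}

#' @rdname het_hom_ratio
#' @export
het_hom_table <- function(cs) {
  purrr::map_dfr(call_set_samples(cs), function(s) {
    cls <- genotype_class(cs[[paste0("gt_", s)]])
    tibble(
      sample = s,
      n_het = sum(cls == "het"),
      n_hom_alt = sum(cls == "hom_alt"),
      het_hom = if (sum(cls == "hom_alt") == 0) NA_real_ else
        sum(cls == "het") / sum(cls == "hom_alt")
    )
  })
}

#' @rdname het_hom_ratio
#' @export
mean_het_hom <- function(cs) {
  mean(het_hom_table(cs)$het_hom)
}

#' Count singleton variants
#'
#' A singleton is an allele key whose non-reference genotype occurs in
#' exactly one sample of the analyzed cohort (within-cohort definition; no
#' external database is consulted).
#'
#' @param cs A multi-sample call set.
#' @return Integer count.
#' @export
singleton_count <- function(cs) {
  if (nrow(as_tibble(cs)) == 0) return(0L)
  cls <- gt_class_matrix(cs)
  carriers <- rowSums(cls == "het" | cls == "hom_alt")
  sum(carriers == 1L)
}

#' Count multiallelic sites
#'
#' Number of distinct (contig, pos, ref) sites among records flagged as
#' decomposed from a multiallelic representation. Because trimming is
#' applied per decomposed allele, alleles of one original site can
#' normalize to different (pos, ref) anchors and are then counted as
#' separate sites; for multiallelic SNV sites the count is exact.
#'
#' @param cs A call set.
#' @return Integer count.
#' @export
multiallelic_site_count <- function(cs) {
  ma <- as_tibble(cs)[cs$multiallelic_origin, c("contig", "pos", "ref")]
  nrow(dplyr::distinct(ma))
}

#' Summarise a call set
#'
#' One-row summary mirroring published call-set characterization tables:
#' SNV/indel/MNV counts, transitions and transversions with Ts/Tv,
#' deletion and insertion counts with del/ins, singleton counts per
#' stratum, multiallelic-site count and the averaged het/hom ratio.
#' Also available as `glance()` on a call set.
#'
#' @param cs A call set.
#' @return A one-row tibble.
#' @export
callset_summary <- function(cs) {
  cls <- classify_allele(cs$ref, cs$alt)
  snv <- cs_filter(cs, cls == "snv")
  indel <- cs_filter(cs, cls %in% c("insertion", "deletion"))
  ts <- sum(is_transition(snv$ref, snv$alt))
  tv <- nrow(snv) - ts
  n_del <- sum(classify_allele(indel$ref, indel$alt) == "deletion")
  n_ins <- nrow(indel) - n_del
  tibble(
    n_records = nrow(as_tibble(cs)),
    n_snv = nrow(snv),
    n_indel = nrow(indel),
    n_mnv = sum(cls == "mnv"),
    ts = ts,
    tv = tv,
    ts_tv = if (tv == 0) NA_real_ else ts / tv,
    n_del = n_del,
    n_ins = n_ins,
    del_ins = if (n_ins == 0) NA_real_ else n_del / n_ins,
    n_singleton_snv = singleton_count(snv),
    n_singleton_indel = singleton_count(indel),
    n_multiallelic_sites = multiallelic_site_count(cs),
    het_hom_mean = if (length(call_set_samples(cs)) == 0) NA_real_ else
      mean_het_hom(cs)
  )
}

#' Single-nucleotide substitution spectrum
#'
#' Counts a sample's non-reference SNV calls in each of the twelve ordered
#' `ref>alt` classes and scales them to calls per 10 Mb:
#' `rate = count / (genome_size / 1e7)`, with Poisson standard error
#' `sqrt(count)` scaled identically. With `sample = NULL` the per-sample
#' class counts are averaged across all samples before scaling (the
#' cohort-mean spectrum).
#'
#' @param cs A call set.
#' @param sample Sample name, or `NULL` for the cohort mean.
#' @param genome_size Genome size in base pairs used as the rate
#'   denominator. There is no default: supply the size of the genome the
#'   calls were made against.
#' @return A `spectrum_result` tibble with columns `class`, `count`,
#'   `rate_per_10mb`, `poisson_se` and attributes `genome_size`, `sample`.
#' @export
substitution_spectrum <- function(cs, sample = NULL, genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1 ||
      is.na(genome_size) || genome_size <= 0) {
    abort("`genome_size` must be a single positive number of base pairs.")
  }
  snv <- cs_filter(cs, classify_allele(cs$ref, cs$alt) == "snv")
  classes <- substitution_classes()
  count_for <- function(s) {
    carried <- sample_variant_records(snv, s)
    tab <- table(factor(paste0(carried$ref, ">", carried$alt),
                        levels = classes))
    as.numeric(tab)
  }
  count <- if (is.null(sample)) {
    samples <- call_set_samples(snv)
    if (length(samples) == 0) {
      abort("Call set has no samples; supply genotyped records.")
    }
    rowMeans(vapply(samples, count_for, numeric(length(classes))))
  } else {
    count_for(sample)
  }
  scale <- genome_size / 1e7
  out <- tibble(
    class = factor(classes, levels = classes),
    count = count,
    rate_per_10mb = count / scale,
    poisson_se = sqrt(count) / scale
  )
  structure(out,
            class = c("spectrum_result", class(out)),
            genome_size = genome_size,
            sample = sample %||% NA_character_)
}

#' Contrast two substitution spectra
#'
#' Per-class rate differences and ratios between two spectra computed with
#' the same genome size, e.g. a fresh-frozen baseline (`a`) against an
#' FFPE call set (`b`). FFPE cytosine deamination shows up as ratios above
#' 1 concentrated in the C>T and G>A classes.
#'
#' @param a,b `spectrum_result` objects with identical `genome_size`.
#' @return A `spectrum_contrast` tibble with per-class `rate_a`, `rate_b`,
#'   `rate_diff` (b - a) and `rate_ratio` (b / a, `NA` for zero baseline).
#' @export
spectrum_contrast <- function(a, b) {
  ga <- attr(a, "genome_size")
  gb <- attr(b, "genome_size")
  if (!isTRUE(all.equal(ga, gb))) {
    abort("Spectra were computed with different genome sizes.")
  }
  out <- tibble(
    class = a$class,
    count_a = a$count,
    count_b = b$count,
    rate_a = a$rate_per_10mb,
    rate_b = b$rate_per_10mb,
    rate_diff = b$rate_per_10mb - a$rate_per_10mb,
    rate_ratio = ifelse(a$rate_per_10mb > 0,
                        b$rate_per_10mb / a$rate_per_10mb, NA_real_)
  )
  structure(out,
            class = c("spectrum_contrast", class(out)),
            genome_size = ga)
}
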