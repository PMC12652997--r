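#' Construct a call set
#'
#' A call set is a tibble of decomposed, trimmed allele-level variant
#' records with one column per sample genotype. It is the common currency of
#' the package: [read_vcf()] produces one, the comparison, statistics,
#' filtering and prioritization functions consume them, and the simulators
#' generate them.
#'
#' Required columns are `contig`, `pos`, `ref`, `alt`; recognised optional
#' columns are `qual`, `filter`, `multiallelic_origin`, `impact`, the site
#' annotations `QD`, `SOR`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`, and
#' one `gt_<sample>` column per sample holding canonical GT strings
#' (`"0/0"`, `"0/1"`, `"1/1"`, `"./."`). Missing optional columns are filled
#' with `NA`/defaults. Each allele key (contig, pos, ref, alt) may appear at
#' most once.
#'
#' @param records A data frame of variant records.
#' @param provenance Optional free-text label (caller name, tissue type).
#' @return A `call_set`: a tibble with the columns above, class `call_set`
#'   and a `provenance` attribute.
#' @export
#' @examples
#' call_set(
#'   tibble::tibble(
#'     contig = "chr1", pos = c(100L, 200L), ref = "A", alt = c("G", "T"),
#'     gt_S1 = c("0/1", "1/1")
#'   ),
#'   provenance = "toy"
#' )
call_set <- function(records, provenance = NULL) {
  x <- as_tibble(records)
  for (col in c("contig", "pos", "ref", "alt")) {
    if (!col %in% names(x)) {
      abort(paste0("Call-set records need a `", col, "` column."))
    }
  }
  x$contig <- as.character(x$contig)
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(as.character(x$ref))
  x$alt <- toupper(as.character(x$alt))
  if (any(x$pos < 1L, na.rm = TRUE)) abort("Positions must be >= 1.")
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ.")
  if (!"qual" %in% names(x)) x$qual <- NA_real_
  x$qual <- as.numeric(x$qual)
  if (!"filter" %in% names(x)) x$filter <- "."
  if (!"multiallelic_origin" %in% names(x)) x$multiallelic_origin <- FALSE
  if (!"impact" %in% names(x)) x$impact <- NA_character_
  bad_impact <- !is.na(x$impact) &
    !x$impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (any(bad_impact)) {
    abort("`impact` must be HIGH, MODERATE, LOW, MODIFIER or NA.")
  }
  for (key in annotation_keys()) {
    if (!key %in% names(x)) x[[key]] <- NA_real_
    x[[key]] <- as.numeric(x[[key]])
  }
  gt_cols <- grep("^gt_", names(x), value = TRUE)
  for (col in gt_cols) x[[col]] <- as.character(x[[col]])
  front <- c("contig", "pos", "ref", "alt", "qual", "filter",
             "multiallelic_origin", "impact", annotation_keys())
  x <- x[c(front, gt_cols)]
  if (anyDuplicated(variant_key(x))) {
    abort("Duplicate allele keys (contig, pos, ref, alt) in call set.")
  }
  new_call_set(x, provenance)
}

new_call_set <- function(x, provenance = NULL) {
  structure(
    x,
    class = unique(c("call_set", class(as_tibble(x)))),
    provenance = provenance %||% NA_character_
  )
}

# subset rows of a call set, preserving class and attributes
cs_filter <- function(cs, keep) {
  out <- as_tibble(cs)[keep, , drop = FALSE]
  new_call_set(out, attr(cs, "provenance"))
}

#' Sample names of a call set
#'
#' @param x A call set (or any data frame with `gt_<sample>` columns).
#' @return Character vector of sample names.
#' @export
call_set_samples <- function(x) {
  sub("^gt_", "", grep("^gt_", names(x), value = TRUE))
}

#' @export
print.call_set <- function(x, ...) {
  cls <- classify_allele(x$ref, x$alt)
  cat(sprintf(
    "<call_set> %d records (%d SNV, %d ins, %d del, %d MNV), %d sample(s)\n",
    nrow(x), sum(cls == "snv"), sum(cls == "insertion"),
    sum(cls == "deletion"), sum(cls == "mnv"), length(call_set_samples(x))
  ))
  prov <- attr(x, "provenance")
  if (!is.na(prov)) cat("provenance:", prov, "\n")
  NextMethod()
  invisible(x)
}

# genotype-class matrix (records x samples)
gt_class_matrix <- function(cs, samples = call_set_samples(cs)) {
  out <- vapply(
    samples,
    function(s) genotype_class(cs[[paste0("gt_", s)]]),
    character(nrow(cs))
  )
  matrix(out, nrow = nrow(cs), dimnames = list(NULL, samples))
}

# allele keys (tibble form) of records carried by `sample` (het or hom_alt)
sample_variant_records <- function(cs, sample) {
  if (!sample %in% call_set_samples(cs)) {
    abort(paste0("Sample `", sample, "` is not in the call set."))
  }
  cls <- genotype_class(cs[[paste0("gt_", sample)]])
  cs_filter(cs, cls %in% c("het", "hom_alt"))
}
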