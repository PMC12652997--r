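# GATK-style hard filtering. A record fails a criterion only when the
# annotation is present AND strictly violates the inequality; boundary
# values pass and absent annotations are skipped, never failed (failing on
# absence would mass-fail records that lack rank-sum annotations because
# no heterozygote informs them).

#' Hard-filter thresholds
#'
#' Default cutoffs for GATK-style hard filtering of germline short-variant
#' calls. A record fails `QD` when `QD < QD_min`, `QUAL` when
#' `QUAL < QUAL_min`, `SOR` when `SOR > SOR_max`, `FS` when `FS > FS_max`,
#' `MQ` when `MQ < MQ_min`, `MQRankSum` when `MQRankSum < MQRankSum_min`
#' and `ReadPosRankSum` when `ReadPosRankSum < ReadPosRankSum_min`; the
#' inequalities are strict, so boundary values pass. SNV defaults:
#' QD 2.0, QUAL 30.0, SOR 3.0, FS 60.0, MQ 40.0, MQRankSum -12.5,
#' ReadPosRankSum -8.0. Indel defaults: QD 2.0, QUAL 30.0, FS 200.0,
#' ReadPosRankSum -20.0, SOR 10.
#'
#' @param snv,indel Named lists overriding individual defaults.
#' @return A `filter_thresholds` object.
#' @export
#' @examples
#' filter_thresholds(snv = list(QUAL_min = 50))
filter_thresholds <- function(snv = list(), indel = list()) {
  d_snv <- list(QD_min = 2.0, QUAL_min = 30.0, SOR_max = 3.0, FS_max = 60.0,
                MQ_min = 40.0, MQRankSum_min = -12.5,
                ReadPosRankSum_min = -8.0)
  d_indel <- list(QD_min = 2.0, QUAL_min = 30.0, FS_max = 200.0,
                  ReadPosRankSum_min = -20.0, SOR_max = 10)
  check <- function(user, defaults, which) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("Unknown ", which, " threshold(s): ",
                   paste(unknown, collapse = ", ")))
    }
    out <- modifyList(defaults, user)
    if (!all(vapply(out, function(v) is.numeric(v) && is.finite(v),
                    logical(1)))) {
      abort("All thresholds must be finite numbers.")
    }
    out
  }
  structure(
    list(snv = check(snv, d_snv, "SNV"),
         indel = check(indel, d_indel, "indel")),
    class = "filter_thresholds"
  )
}

# criterion label -> record column, direction and threshold name
criterion_table <- function() {
  tribble(
    ~label,            ~column,           ~direction, ~threshold,
    "QD",              "QD",              "min",      "QD_min",
    "QUAL",            "qual",            "min",      "QUAL_min",
    "SOR",             "SOR",             "max",      "SOR_max",
    "FS",              "FS",              "max",      "FS_max",
    "MQ",              "MQ",              "min",      "MQ_min",
    "MQRankSum",       "MQRankSum",       "min",      "MQRankSum_min",
    "ReadPosRankSum",  "ReadPosRankSum",  "min",      "ReadPosRankSum_min"
  )
}

#' Evaluate hard-filter criteria for every record
#'
#' SNV records are checked against the SNV thresholds and
#' insertion/deletion records against the indel thresholds; MNV records
#' use the SNV thresholds. Criteria whose annotation is absent (`NA`) are
#' listed as skipped and never fail a record.
#'
#' @param x A call set or data frame of records.
#' @param thresholds A [filter_thresholds()] object.
#' @return A tibble with one row per record: `passed` (logical),
#'   `failed_criteria` and `skipped_criteria` (`;`-joined labels, `""`
#'   when empty).
#' @export
evaluate_filters <- function(x, thresholds = filter_thresholds()) {
  x <- as_tibble(x)
  n <- nrow(x)
  cls <- classify_allele(x$ref, x$alt)
  use_snv <- cls %in% c("snv", "mnv")
  crit <- criterion_table()
  failed <- matrix(FALSE, n, nrow(crit), dimnames = list(NULL, crit$label))
  skipped <- matrix(FALSE, n, nrow(crit), dimnames = list(NULL, crit$label))
  for (i in seq_len(nrow(crit))) {
    col <- crit$column[i]
    val <- if (col %in% names(x)) as.numeric(x[[col]]) else rep(NA_real_, n)
    for (side in c("snv", "indel")) {
      rows <- if (side == "snv") use_snv else !use_snv
      cut <- thresholds[[side]][[crit$threshold[i]]]
      if (is.null(cut)) {
        # criterion not part of this class's filter: neither fail nor skip
        next
      }
      present <- rows & !is.na(val)
      viol <- if (crit$direction[i] == "min") val < cut else val > cut
      failed[, i] <- failed[, i] | (present & viol %in% TRUE)
      skipped[, i] <- skipped[, i] | (rows & is.na(val))
    }
  }
  join <- function(m) {
    apply(m, 1L, function(r) paste(colnames(m)[r], collapse = ";"))
  }
  tibble(
    passed = rowSums(failed) == 0,
    failed_criteria = if (n == 0) character(0) else join(failed),
    skipped_criteria = if (n == 0) character(0) else join(skipped)
  )
}

#' @rdname evaluate_filters
#' @param record A one-row data frame.
#' @return For `evaluate_record()`: a list with `passed`,
#'   `failed_criteria` and `skipped_criteria` (character vectors).
#' @export
evaluate_record <- function(record, thresholds = filter_thresholds()) {
  v <- evaluate_filters(record, thresholds)
  if (nrow(v) != 1) abort("`record` must be a single record.")
  split_labels <- function(s) if (nzchar(s)) strsplit(s, ";")[[1]] else
    character(0)
  list(
    passed = v$passed,
    failed_criteria = split_labels(v$failed_criteria),
    skipped_criteria = split_labels(v$skipped_criteria)
  )
}

#' Apply hard filters to a call set
#'
#' Sets the FILTER column to `PASS` or the `;`-joined labels of the failed
#' criteria, and returns the passing subset for downstream use together
#' with per-class summary counts. With `bypass = TRUE` the call set is
#' returned unchanged (the configuration used for callers whose own model
#' already filters, e.g. DeepVariant output).
#'
#' @param cs A call set.
#' @param thresholds A [filter_thresholds()] object.
#' @param bypass If `TRUE`, no filtering is applied.
#' @return A list with `callset` (passing records only), `annotated` (all
#'   records with FILTER set) and `summary` (tibble of pass/fail counts
#'   per variant class).
#' @export
apply_filters <- function(cs, thresholds = filter_thresholds(),
                          bypass = FALSE) {
  cs <- call_set(cs, attr(cs, "provenance"))
  cls <- classify_allele(cs$ref, cs$alt)
  cls[cls %in% c("insertion", "deletion")] <- "indel"
  if (bypass) {
    summary <- as_tibble(cs) |>
      mutate(class = cls) |>
      count(class, name = "n") |>
      mutate(n_pass = n, n_fail = 0L)
    return(list(callset = cs, annotated = cs, summary = summary))
  }
  verdict <- evaluate_filters(cs, thresholds)
  annotated <- cs
  annotated$filter <- ifelse(verdict$passed, "PASS",
                             verdict$failed_criteria)
  summary <- tibble(class = cls, passed = verdict$passed) |>
    group_by(class) |>
    summarise(n = dplyr::n(), n_pass = sum(passed),
              n_fail = sum(!passed), .groups = "drop")
  list(
    callset = cs_filter(annotated, verdict$passed),
    annotated = annotated,
    summary = summary
  )
}
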