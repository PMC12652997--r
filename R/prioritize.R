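# Autosomal-recessive candidate-variant prioritization: an affected case
# must be homozygous alternate (1/1) while every control is homozygous
# reference (0/0) or missing (./.). A het or hom-alt control excludes the
# key; a missing control genotype does not, and keys absent from the
# control call set are treated as missing in all controls (joint-genotyping
# absence is unobservable downstream of caller output -- the permissive
# choice, documented).

#' Construct a normalized interval set
#'
#' Intervals are held 1-based inclusive. Overlapping intervals on the same
#' contig are merged; the total span in bp is available via
#' [interval_span()]. BED input (0-based half-open) is converted by
#' [read_bed()].
#'
#' @param x A data frame with columns `contig`, `start`, `end` (1-based
#'   inclusive).
#' @return An `interval_set` tibble with attribute `total_span`.
#' @export
interval_set <- function(x) {
  x <- as_tibble(x)[c("contig", "start", "end")]
  x$contig <- as.character(x$contig)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(is.na(x$start) | is.na(x$end) | x$end < x$start | x$start < 1)) {
    abort("Intervals must satisfy 1 <= start <= end.")
  }
  x <- arrange(x, .data$contig, .data$start, .data$end)
  merged <- x |>
    group_by(.data$contig) |>
    mutate(new_block = is.na(lag(cummax(.data$end))) |
             .data$start > lag(cummax(.data$end))) |>
    mutate(block = cumsum(.data$new_block)) |>
    group_by(.data$contig, .data$block) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("contig", "start", "end") |>
    arrange(.data$contig, .data$start)
  structure(
    merged,
    class = c("interval_set", class(merged)),
    total_span = sum(as.numeric(merged$end) - merged$start + 1)
  )
}

#' @rdname interval_set
#' @param iv An `interval_set`.
#' @return For `interval_span()`: the total bp covered.
#' @export
interval_span <- function(iv) {
  attr(iv, "total_span") %||% sum(as.numeric(iv$end) - iv$start + 1)
}

# key tibble helper: the four identity columns
key_cols <- function(x) {
  as_tibble(x)[c("contig", "pos", "ref", "alt")]
}

#' Case-private homozygous-alternate variants
#'
#' Allele keys at which the affected case carries a homozygous alternate
#' genotype while every control genotype is homozygous reference or
#' missing. Keys absent from the control call set count as missing in all
#' controls.
#'
#' @param case_cs Call set containing the affected samples.
#' @param case Name of the affected sample.
#' @param controls Control-cohort call set (may share no samples with
#'   `case_cs`), or `NULL` for no controls.
#' @return A tibble of allele keys (`contig`, `pos`, `ref`, `alt`).
#' @export
private_hom_alt <- function(case_cs, case, controls = NULL) {
  if (!case %in% call_set_samples(case_cs)) {
    abort(paste0("Case sample `", case, "` is not in the call set."))
  }
  cand <- cs_filter(
    case_cs, genotype_class(case_cs[[paste0("gt_", case)]]) == "hom_alt"
  )
  keys <- key_cols(cand)
  if (is.null(controls) || nrow(as_tibble(controls)) == 0 ||
      length(call_set_samples(controls)) == 0) {
    return(keys)
  }
  ctrl_cls <- gt_class_matrix(controls)
  has_carrier <- rowSums(ctrl_cls == "het" | ctrl_cls == "hom_alt") > 0
  hit <- match(variant_key(keys), variant_key(controls))
  keep <- is.na(hit) | !has_carrier[hit]
  keys[keep, , drop = FALSE]
}

#' Intersect per-case key sets
#'
#' @param per_case_keys A list of allele-key tibbles (one per case).
#' @return The keys shared by all cases.
#' @export
shared_private <- function(per_case_keys) {
  if (length(per_case_keys) == 0) abort("At least one case is required.")
  purrr::reduce(lapply(per_case_keys, key_cols), dplyr::intersect)
}

#' Keep protein-changing keys
#'
#' Protein-changing means an annotation impact of MODERATE or HIGH (the
#' snpEff convention). Keys with missing impact, or absent from the
#' annotated call set, are dropped.
#'
#' @param keys An allele-key tibble.
#' @param cs The call set carrying `impact` annotations.
#' @return The filtered key tibble.
#' @export
filter_protein_changing <- function(keys, cs) {
  keys <- key_cols(keys)
  hit <- match(variant_key(keys), variant_key(cs))
  impact <- cs$impact[hit]
  keys[!is.na(impact) & impact %in% c("MODERATE", "HIGH"), , drop = FALSE]
}

#' Keep keys on configured autosomes
#'
#' Sex chromosomes and unplaced contigs are excluded by listing only the
#' autosomes. The list must be configured explicitly: an empty list is an
#' error, not "keep everything".
#'
#' @param keys An allele-key tibble.
#' @param autosome_names Character vector of autosomal contig names.
#' @return The filtered key tibble.
#' @export
filter_autosomes <- function(keys, autosome_names) {
  if (length(autosome_names) == 0) {
    abort("`autosome_names` must list at least one contig.")
  }
  keys <- key_cols(keys)
  keys[keys$contig %in% autosome_names, , drop = FALSE]
}

#' Keep keys inside an interval set
#'
#' A key is kept when its position falls inside any interval on the
#' matching contig; both interval ends are inclusive.
#'
#' @param keys An allele-key tibble.
#' @param iv An [interval_set()].
#' @return The filtered key tibble.
#' @export
filter_interval <- function(keys, iv) {
  keys <- key_cols(keys)
  if (nrow(keys) == 0 || nrow(iv) == 0) {
    return(keys[integer(0), , drop = FALSE])
  }
  hits <- keys |>
    mutate(.row = dplyr::row_number()) |>
    inner_join(as_tibble(iv), by = "contig",
               relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end)
  keys[sort(unique(hits$.row)), , drop = FALSE]
}

#' Run the full recessive-disease prioritization cascade
#'
#' Applies the tiers in order for each case and for the across-case
#' intersection ("shared"): all homozygous-alternate variants, private
#' (absent from all controls), protein-changing (impact MODERATE/HIGH),
#' autosomal, and inside the critical interval. Counts are monotonically
#' non-increasing down the tiers.
#'
#' @param case_cs Call set of the affected samples (with `impact`
#'   annotations).
#' @param controls Control-cohort call set, or `NULL`.
#' @param cases Affected sample names (default: all samples of `case_cs`).
#' @param intervals An [interval_set()] with the critical interval(s).
#' @param autosomes Character vector of autosomal contig names.
#' @return A `prioritization_report`: list with `counts` (tibble of
#'   tier x sample counts, samples plus `"shared"`), `keys` (nested list
#'   of surviving allele-key tibbles) and `cases`.
#' @export
prioritize <- function(case_cs, controls = NULL, cases = NULL,
                       intervals, autosomes) {
  cases <- cases %||% call_set_samples(case_cs)
  if (length(cases) == 0) abort("At least one case sample is required.")
  tiers <- c("total", "private", "private_protein_changing",
             "private_protein_changing_autosomal",
             "private_protein_changing_in_interval")
  per_case <- lapply(cases, function(s) {
    total <- key_cols(cs_filter(
      case_cs, genotype_class(case_cs[[paste0("gt_", s)]]) == "hom_alt"
    ))
    private <- private_hom_alt(case_cs, s, controls)
    pc <- filter_protein_changing(private, case_cs)
    auto <- filter_autosomes(pc, autosomes)
    iv <- filter_interval(auto, intervals)
    setNames(list(total, private, pc, auto, iv), tiers)
  })
  names(per_case) <- cases
  shared <- lapply(tiers, function(tier) {
    shared_private(lapply(per_case, `[[`, tier))
  })
  names(shared) <- tiers
  keys <- lapply(tiers, function(tier) {
    c(lapply(per_case, `[[`, tier), list(shared = shared[[tier]]))
  })
  names(keys) <- tiers
  counts <- purrr::map_dfr(tiers, function(t) {
    n_vec <- vapply(keys[[t]], nrow, integer(1))
    tibble(tier = t, sample = names(n_vec), n = unname(n_vec))
  })
  counts$tier <- factor(counts$tier, levels = tiers)
  structure(
    list(counts = counts, keys = keys, cases = cases),
    class = "prioritization_report"
  )
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("<prioritization_report>", length(x$cases), "case(s)\n")
  wide <- tidyr::pivot_wider(x$counts, names_from = "sample",
                             values_from = "n")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}
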