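# VCF input goes through vcfR; multiallelic sites are decomposed into
# allele-level records on read, genotypes re-coded relative to the focal
# alternate allele, and alleles trimmed to canonical form. Output is a
# small self-contained VCFv4.2 serializer over the already-decomposed
# records; decomposition provenance is preserved through an
# OLD_MULTIALLELIC INFO flag (bcftools-norm style) so call sets round-trip.

#' Read a VCF file into a call set
#'
#' Reads a VCF v4.x file (plain, gzip or bgzip), decomposes multiallelic
#' sites into allele-level records, trims alleles to canonical form and
#' normalizes genotypes to the focal alternate allele. The snpEff-style
#' `ANN` INFO field, when present, is parsed into the `impact` column
#' (third pipe-delimited subfield of the first annotation). The site
#' annotations QD, SOR, FS, MQ, MQRankSum and ReadPosRankSum are parsed
#' when present.
#'
#' Records whose alternate allele is symbolic (`*`, `<DEL>`, ...) or
#' missing are dropped with a warning. Contig names are taken verbatim: no
#' "chr" harmonization is attempted, so comparing call sets from different
#' naming conventions yields an empty intersection.
#'
#' @param path Path to a VCF file with a GT FORMAT field.
#' @param sample_subset Optional character vector of sample names to keep.
#' @param provenance Optional label stored on the call set (defaults to the
#'   file name).
#' @return A [call_set()].
#' @export
read_vcf <- function(path, sample_subset = NULL, provenance = NULL) {
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    abort(paste0("VCF file contains no variant records: ", path))
  }
  if (!"FORMAT" %in% colnames(v@gt) ||
      !all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    abort("VCF records must carry a GT FORMAT field.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing) > 0) {
      abort(paste0("Sample(s) not present in VCF: ",
                   paste(missing, collapse = ", ")))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  info <- fix[, "INFO"]
  ann <- vcfR::extract.info(v, element = "ANN")
  raw <- tibble(
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    old_multiallelic = grepl("(^|;)OLD_MULTIALLELIC(;|=|$)", info),
    impact = impact_from_ann(ann)
  )
  for (key in annotation_keys()) {
    raw[[key]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = key))
    )
  }

  # decompose: one output row per alternate allele
  alt_split <- strsplit(ifelse(is.na(raw$alt), "", raw$alt), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  n_alt[n_alt == 0L] <- 1L
  alt_split[lengths(alt_split) == 0L] <- list(NA_character_)
  idx <- rep(seq_len(nrow(raw)), n_alt)
  focal <- sequence(n_alt)
  alt_k <- toupper(unlist(alt_split, use.names = FALSE))

  keep <- !is.na(alt_k) & grepl("^[ACGTN]+$", alt_k)
  if (!all(keep)) {
    warn(sprintf("Dropping %d record(s) with symbolic or missing ALT allele.",
                 sum(!keep)))
    idx <- idx[keep]
    focal <- focal[keep]
    alt_k <- alt_k[keep]
  }
  if (length(idx) == 0) {
    abort("No usable variant records after removing symbolic alleles.")
  }

  out <- raw[idx, c("contig", "qual", "filter", "impact", annotation_keys())]
  trimmed <- trim_redundant_bases(raw$pos[idx], raw$ref[idx], alt_k)
  out$pos <- trimmed$pos
  out$ref <- trimmed$ref
  out$alt <- trimmed$alt
  out$multiallelic_origin <- n_alt[idx] > 1L | raw$old_multiallelic[idx]
  for (s in samples) {
    out[[paste0("gt_", s)]] <- normalize_gt(gt[idx, s], focal)
  }

  dup <- duplicated(variant_key(out))
  if (any(dup)) {
    warn(sprintf("Collapsing %d duplicate allele key(s); keeping first.",
                 sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  call_set(out, provenance = provenance %||% basename(path))
}

# impact = 3rd pipe-delimited subfield of the first ANN annotation
impact_from_ann <- function(ann) {
  first <- sub(",.*$", "", ann)
  fields <- stringr::str_split_fixed(first, "\\|", 4L)
  imp <- fields[, 3L]
  imp[!imp %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")] <- NA_character_
  imp
}

#' Write a call set to a VCF file
#'
#' Writes decomposed allele-level records as a VCF v4.2 file, one line per
#' record, sorted by (contig, pos, ref, alt) for byte-deterministic output.
#' Records flagged `multiallelic_origin` carry an `OLD_MULTIALLELIC` INFO
#' flag; `impact` is emitted as a minimal snpEff-dialect `ANN` entry; the
#' numeric site annotations are written when non-missing. A `.gz` suffix
#' produces gzip-compressed output.
#'
#' @param cs A [call_set()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @param genome Optional [genome_model()] used to emit `##contig` header
#'   lines with lengths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path, genome = NULL) {
  cs <- call_set(cs, attr(cs, "provenance"))
  samples <- call_set_samples(cs)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ffpebench",
    if (!is.null(genome)) {
      sprintf("##contig=<ID=%s,length=%d>", genome$name,
              as.integer(genome$length))
    },
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,",
                   "Description=\"Site annotation\">"), annotation_keys()),
    paste0("##INFO=<ID=OLD_MULTIALLELIC,Number=0,Type=Flag,",
           "Description=\"Record decomposed from a multiallelic site\">"),
    paste0("##INFO=<ID=ANN,Number=.,Type=String,",
           "Description=\"Functional annotations: ",
           "'Allele | Annotation | Annotation_Impact | Gene_Name'\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(cs$contig, cs$pos, cs$ref, cs$alt, method = "radix")
  x <- as_tibble(cs)[ord, , drop = FALSE]

  info <- vapply(seq_len(nrow(x)), function(i) {
    parts <- character(0)
    for (key in annotation_keys()) {
      val <- x[[key]][i]
      if (!is.na(val)) parts <- c(parts, sprintf("%s=%.6g", key, val))
    }
    if (isTRUE(x$multiallelic_origin[i])) {
      parts <- c(parts, "OLD_MULTIALLELIC")
    }
    if (!is.na(x$impact[i])) {
      parts <- c(parts,
                 sprintf("ANN=%s|custom|%s|", x$alt[i], x$impact[i]))
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))

  gt_cols <- paste0("gt_", samples)
  body <- if (nrow(x) == 0) character(0) else {
    body_mat <- cbind(
      x$contig, as.character(x$pos), rep(".", nrow(x)), x$ref, x$alt,
      ifelse(is.na(x$qual), ".", sprintf("%.6g", x$qual)),
      ifelse(is.na(x$filter) | x$filter == "", ".", x$filter),
      info, rep("GT", nrow(x)),
      as.matrix(x[gt_cols])
    )
    apply(body_mat, 1L, paste, collapse = "\t")
  }

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED input is 0-based half-open; intervals are converted to the 1-based
#' inclusive convention used internally and normalized via [interval_set()].
#'
#' @param path Path to a BED file (first three columns used).
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  raw <- raw[!grepl("^(track|browser)", raw[[1]]), , drop = FALSE]
  if (nrow(raw) == 0 || ncol(raw) < 3) {
    abort("BED file must have at least three columns (contig, start, end).")
  }
  interval_set(tibble(
    contig = raw[[1]],
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]])
  ))
}
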