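# The allele-level matching unit used throughout is the trimmed tuple
# (contig, pos, ref, alt): shared trailing bases are removed first, then
# shared leading bases with the position advanced. No reference-FASTA
# left-alignment is attempted, so repeat-region indels from different
# callers may normalize to different keys (documented limitation).

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base; the other two substitutions are
# transversions
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' The twelve substitution classes
#'
#' Ordered `ref>alt` labels for single-nucleotide substitutions, in the fixed
#' display order used by substitution-spectrum results (A>C, A>G, ..., T>G).
#' Strand-symmetric collapsing to six classes is deliberately not applied:
#' FFPE cytosine deamination shows up as an excess of C>T and of G>A calls,
#' which a collapsed spectrum would merge.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' substitution_classes()
substitution_classes <- function() {
  paste0(rep(DNA_BASES, each = 3),
         ">",
         unlist(lapply(DNA_BASES, function(b) setdiff(DNA_BASES, b))))
}

annotation_keys <- function() {
  c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
}

#' Trim shared redundant bases from a ref/alt allele pair
#'
#' Reduces VCF allele pairs to a canonical trimmed form so that the same
#' underlying edit reported by two callers (or at two decomposed alleles of
#' one site) maps to the same allele key. Shared trailing bases are removed
#' first, then shared leading bases with `pos` incremented accordingly; at
#' least one base always remains in each allele.
#'
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of alleles (A/C/G/T/N), same length as
#'   `pos`.
#' @return A tibble with columns `pos`, `ref`, `alt` in trimmed form.
#' @export
#' @examples
#' trim_redundant_bases(100, "CT", "CA")   # -> 101, T, A
#' trim_redundant_bases(100, "ACC", "AC")  # -> 100, AC, A
trim_redundant_bases <- function(pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (length(ref) != length(alt) || length(pos) != length(ref)) {
    abort("`pos`, `ref` and `alt` must have the same length.")
  }
  if (length(pos) == 0) {
    return(tibble(pos = integer(), ref = character(), alt = character()))
  }
  if (any(is.na(ref) | is.na(alt) | !nzchar(ref) | !nzchar(alt))) {
    abort("Alleles must be non-empty DNA strings.")
  }
  if (any(grepl("[^ACGTN]", ref)) || any(grepl("[^ACGTN]", alt))) {
    abort("Alleles may only contain A, C, G, T or N.")
  }
  rl <- nchar(ref)
  al <- nchar(alt)
  # shared trailing bases
  repeat {
    can <- rl > 1L & al > 1L &
      substr(ref, rl, rl) == substr(alt, al, al)
    if (!any(can)) break
    rl[can] <- rl[can] - 1L
    al[can] <- al[can] - 1L
  }
  ref <- substr(ref, 1L, rl)
  alt <- substr(alt, 1L, al)
  # shared leading bases, advancing pos
  repeat {
    can <- rl > 1L & al > 1L &
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2L, rl[can])
    alt[can] <- substr(alt[can], 2L, al[can])
    rl[can] <- rl[can] - 1L
    al[can] <- al[can] - 1L
    pos[can] <- pos[can] + 1L
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

#' Classify a trimmed allele pair
#'
#' @param ref,alt Character vectors of trimmed alleles.
#' @return Character vector with values `"snv"`, `"insertion"`, `"deletion"`
#'   or `"mnv"`.
#' @export
#' @examples
#' classify_allele(c("A", "A", "ATG", "AT"), c("G", "AT", "A", "GC"))
classify_allele <- function(ref, alt) {
  rl <- nchar(ref)
  al <- nchar(alt)
  dplyr::case_when(
    rl == 1L & al == 1L ~ "snv",
    al > rl ~ "insertion",
    rl > al ~ "deletion",
    .default = "mnv"
  )
}

is_transition <- function(ref, alt) {
  ref %in% DNA_BASES & !is.na(alt) & TRANSITION_PARTNER[ref] == alt
}

# canonical string form of the allele key, used for set operations
variant_key <- function(x) {
  paste(x$contig, x$pos, x$ref, x$alt, sep = "\r")
}
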