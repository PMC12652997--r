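# Genotype semantics: diploid GT strings, phase ignored, allele pair
# treated as an unordered multiset. Any genotype containing a missing
# allele index (".", "./1", NA) is classed missing -- the conservative
# reading of the 0/0-vs-1/1-vs-./. recessive-filtering rule. After
# multiallelic decomposition indices are interpreted relative to a focal
# alternate allele; non-focal alternate alleles count as reference for
# that record.

#' Classify diploid genotype calls
#'
#' @param gt Character vector of VCF GT strings (`"0/1"`, `"1|0"`, `"./."`,
#'   `NA`, ...). Phase separators are ignored.
#' @param focal_alt Integer allele index regarded as "the" alternate allele
#'   of the record (1 after biallelic decomposition). Other alternate
#'   indices are treated as reference.
#' @return Character vector with values `"hom_ref"`, `"het"`, `"hom_alt"` or
#'   `"missing"`.
#' @export
#' @examples
#' genotype_class(c("0/0", "0/1", "1|0", "1/1", "./1", NA))
#' genotype_class("1/2", focal_alt = 2) # het for the focal allele
genotype_class <- function(gt, focal_alt = 1L) {
  gt <- as.character(gt)
  # fast path for the canonical strings the package itself produces
  if (length(focal_alt) == 1L && focal_alt == 1L) {
    lut <- c("0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
             "1/1" = "hom_alt", "./." = "missing")
    out <- unname(lut[gt])
    out[is.na(gt)] <- "missing"
    if (!anyNA(out)) return(out)
  }
  parts <- stringr::str_split_fixed(gt, "[/|]", 2L)
  a1 <- suppressWarnings(as.integer(parts[, 1L]))
  a2 <- suppressWarnings(as.integer(parts[, 2L]))
  missing <- is.na(gt) | is.na(a1) | is.na(a2)
  n_focal <- (a1 == focal_alt) + (a2 == focal_alt)
  dplyr::case_when(
    missing ~ "missing",
    n_focal == 2L ~ "hom_alt",
    n_focal == 1L ~ "het",
    .default = "hom_ref"
  )
}

# canonical unphased GT string relative to the focal alternate allele
normalize_gt <- function(gt, focal_alt = 1L) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[
    genotype_class(gt, focal_alt)
  ]
}

GT_CLASSES <- c("hom_ref", "het", "hom_alt", "missing")
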