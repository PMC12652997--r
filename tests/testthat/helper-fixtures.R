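# Fixtures are built in code; no binary or on-disk test data.

# minimal call-set builder: keys plus per-sample genotype classes
toy_callset <- function(keys, gts, provenance = NULL) {
  df <- tibble::as_tibble(keys)
  for (s in names(gts)) df[[paste0("gt_", s)]] <- gts[[s]]
  call_set(df, provenance = provenance)
}

# random small call set over a handful of sites (for property tests)
random_callset <- function(n, samples = c("A", "B"), seed) {
  withr::with_seed(seed, {
    pool <- tidyr::expand_grid(
      contig = c("chr1", "chr2"),
      pos = 1:60,
      ref = "A", alt = "G"
    )
    idx <- sample(nrow(pool), n)
    gts <- lapply(samples, function(s) {
      sample(c("0/0", "0/1", "1/1", "./."), n, replace = TRUE,
             prob = c(0.25, 0.35, 0.3, 0.1))
    })
    names(gts) <- samples
    toy_callset(pool[idx, ], gts)
  })
}

write_vcf_text <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

mini_vcf_lines <- function() {
  c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Annotation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("chr1", "100", ".", "A", "G", "50", "PASS",
          "QD=12.3;ANN=G|missense_variant|MODERATE|GENE1", "GT", "0/1",
          sep = "\t"),
    paste("chr2", "300", ".", "AT", "A", "99", "PASS", "QD=20", "GT",
          "1/1", sep = "\t")
  )
}

# ---- independent oracles -----------------------------------------------

# apply the edit described by (pos, ref, alt) to a chromosome string
apply_edit <- function(chrom, pos, ref, alt) {
  stopifnot(substr(chrom, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(chrom, 1L, pos - 1L), alt,
         substr(chrom, pos + nchar(ref), nchar(chrom)))
}

# brute-force double-loop sample comparison over all key pairs
brute_compare_sample <- function(truth, query, sample) {
  grab <- function(cs) {
    cls <- genotype_class(cs[[paste0("gt_", sample)]])
    keep <- which(cls %in% c("het", "hom_alt"))
    list(df = tibble::as_tibble(cs)[keep, ], cls = cls[keep])
  }
  t <- grab(truth)
  q <- grab(query)
  tp <- 0L
  concordant <- 0L
  matched_q <- rep(FALSE, nrow(q$df))
  if (nrow(t$df) > 0) {
    for (i in seq_len(nrow(t$df))) {
      for (j in seq_len(nrow(q$df))) {
        same <- t$df$contig[i] == q$df$contig[j] &&
          t$df$pos[i] == q$df$pos[j] &&
          t$df$ref[i] == q$df$ref[j] &&
          t$df$alt[i] == q$df$alt[j]
        if (same) {
          tp <- tp + 1L
          matched_q[j] <- TRUE
          if (t$cls[i] == q$cls[j]) concordant <- concordant + 1L
        }
      }
    }
  }
  tibble::tibble(
    sample = sample,
    truth_total = nrow(t$df), query_total = nrow(q$df),
    tp = tp, fp = nrow(q$df) - tp, fn = nrow(t$df) - tp,
    concordant = concordant
  )
}

# brute-force point-in-interval scan
brute_filter_interval <- function(keys, iv) {
  keys <- tibble::as_tibble(keys)[c("contig", "pos", "ref", "alt")]
  keep <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    for (j in seq_len(nrow(iv))) {
      if (keys$contig[i] == iv$contig[j] &&
          keys$pos[i] >= iv$start[j] && keys$pos[i] <= iv$end[j]) {
        keep[i] <- TRUE
      }
    }
  }
  keys[keep, , drop = FALSE]
}
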