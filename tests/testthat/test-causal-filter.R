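case_key <- tibble::tibble(contig = "chr1", pos = 100L, ref = "A",
                           alt = "G")

one_case <- function(gt) {
  toy_callset(case_key, list(case1 = gt))
}

controls_with <- function(...) {
  gts <- list(...)
  toy_callset(case_key, gts)
}

test_that("private means hom-alt case and no carrier control", {
  cs <- one_case("1/1")
  # all controls 0/0: retained
  ctrl <- controls_with(c1 = "0/0", c2 = "0/0")
  expect_equal(nrow(private_hom_alt(cs, "case1", ctrl)), 1)
  # one het control: excluded
  ctrl2 <- controls_with(c1 = "0/0", c2 = "0/1")
  expect_equal(nrow(private_hom_alt(cs, "case1", ctrl2)), 0)
  # mixture of 0/0 and ./. controls: retained (missing does not exclude)
  ctrl3 <- controls_with(c1 = "0/0", c2 = "./.", c3 = "./.")
  expect_equal(nrow(private_hom_alt(cs, "case1", ctrl3)), 1)
  # key absent from the control call set: treated as missing, retained
  ctrl4 <- toy_callset(
    tibble::tibble(contig = "chr2", pos = 5L, ref = "C", alt = "T"),
    list(c1 = "0/1")
  )
  expect_equal(nrow(private_hom_alt(cs, "case1", ctrl4)), 1)
  # het case genotype is not hom-alt: never a candidate
  expect_equal(nrow(private_hom_alt(one_case("0/1"), "case1", ctrl)), 0)
  expect_error(private_hom_alt(cs, "nope", ctrl), "nope")
})

test_that("shared keys are the intersection across cases", {
  k <- function(pos) tibble::tibble(contig = "chr1", pos = pos,
                                    ref = "A", alt = "G")
  expect_equal(nrow(shared_private(list(k(1:3), k(1:3)))), 3)
  expect_equal(nrow(shared_private(list(k(1:3), k(4:6)))), 0)
  got <- shared_private(list(k(c(1, 2, 3, 4)), k(c(2, 3, 5)),
                             k(c(2, 3, 4, 6))))
  expect_equal(sort(got$pos), c(2L, 3L))
})

test_that("protein-changing keeps MODERATE and HIGH impacts only", {
  df <- tibble::tibble(
    contig = "chr1", pos = 1:4, ref = "A", alt = "G",
    impact = c("HIGH", "MODERATE", "LOW", NA),
    gt_S = "1/1"
  )
  cs <- call_set(df)
  got <- filter_protein_changing(df[1:4, ], cs)
  expect_equal(sort(got$pos), c(1L, 2L))
})

test_that("autosome filtering needs a configured contig list", {
  keys <- tibble::tibble(contig = c("chr1", "chrX", "chrUn_scaffold1"),
                         pos = 1L, ref = "A", alt = "G")
  got <- filter_autosomes(keys, c("chr1", "chr2"))
  expect_equal(got$contig, "chr1")
  expect_error(filter_autosomes(keys, character(0)), "at least one")
})

test_that("interval membership is inclusive at both ends", {
  iv <- interval_set(tibble::tibble(contig = "chr1", start = 100L,
                                    end = 200L))
  keys <- tibble::tibble(contig = "chr1", pos = c(99L, 100L, 200L, 201L),
                         ref = "A", alt = "G")
  got <- filter_interval(keys, iv)
  expect_equal(got$pos, c(100L, 200L))
})

test_that("interval filtering equals the brute-force scan", {
  withr::with_seed(13, {
    for (rep in 1:6) {
      keys <- tibble::tibble(
        contig = sample(c("chr1", "chr2", "chr3"), 40, TRUE),
        pos = sample(1:1000, 40), ref = "A", alt = "G"
      )
      st <- sample(1:800, 4)
      iv <- interval_set(tibble::tibble(
        contig = sample(c("chr1", "chr2"), 4, TRUE),
        start = st,
        end = st + sample(50:200, 4)
      ))
      expect_equal(filter_interval(keys, iv),
                   brute_filter_interval(keys, iv))
    }
  })
})

test_that("overlapping intervals merge and span adds up", {
  iv <- interval_set(tibble::tibble(
    contig = c("chr1", "chr1", "chr2"),
    start = c(100L, 150L, 1L),
    end = c(200L, 300L, 10L)
  ))
  expect_equal(nrow(iv), 2)
  expect_equal(interval_span(iv), 201 + 10)
})

test_that("the planted causal variant survives the full cascade", {
  g <- genome_model()
  coh <- generate_cohort(g, n_controls = 60, seed = 71)
  rep <- prioritize(coh$cases, coh$controls, intervals = coh$interval,
                    autosomes = autosome_names(g))
  final <- rep$keys$private_protein_changing_in_interval$shared
  expect_equal(nrow(dplyr::inner_join(final, coh$planted,
                                      by = c("contig", "pos", "ref",
                                             "alt"))), 1)
})

test_that("with zero controls the private tier equals the hom-alt tier", {
  g <- genome_model()
  coh <- generate_cohort(g, n_controls = 0, seed = 72)
  expect_equal(nrow(coh$controls), 0)
  rep <- prioritize(coh$cases, coh$controls, intervals = coh$interval,
                    autosomes = autosome_names(g))
  counts <- tidyr::pivot_wider(rep$counts, names_from = "sample",
                               values_from = "n")
  expect_equal(counts$case1[counts$tier == "private"],
               counts$case1[counts$tier == "total"])
})

test_that("a single carrier control empties the final tier", {
  cs <- toy_callset(case_key, list(case1 = "1/1", case2 = "1/1"))
  cs$impact <- "HIGH"
  cs <- call_set(cs)
  ctrl <- controls_with(c1 = "0/1")
  iv <- interval_set(tibble::tibble(contig = "chr1", start = 1L,
                                    end = 1000L))
  rep <- prioritize(cs, ctrl, intervals = iv, autosomes = "chr1")
  expect_equal(sum(rep$counts$n[rep$counts$tier == "private"]), 0)
})

test_that("tier counts never increase down the cascade", {
  g <- genome_model()
  for (seed in 73:77) {
    coh <- generate_cohort(g, n_controls = 25, n_background = 400,
                           seed = seed)
    rep <- prioritize(coh$cases, coh$controls, intervals = coh$interval,
                      autosomes = autosome_names(g))
    for (s in unique(rep$counts$sample)) {
      n <- rep$counts$n[rep$counts$sample == s]
      expect_true(all(diff(n) <= 0))
    }
    # shared never exceeds any per-case count at the same tier
    wide <- tidyr::pivot_wider(rep$counts, names_from = "sample",
                               values_from = "n")
    for (cse in coh$cases |> call_set_samples()) {
      expect_true(all(wide$shared <= wide[[cse]]))
    }
  }
})

test_that("adding a control can only shrink the private set", {
  g <- genome_model()
  coh <- generate_cohort(g, n_controls = 30, n_background = 500,
                         seed = 78)
  ctrl_tbl <- tibble::as_tibble(coh$controls)
  sizes <- c(0, 5, 15, 30)
  counts <- vapply(sizes, function(k) {
    keep_cols <- c("contig", "pos", "ref", "alt",
                   paste0("gt_ctrl", seq_len(k)))
    sub <- call_set(ctrl_tbl[intersect(keep_cols, names(ctrl_tbl))])
    nrow(private_hom_alt(coh$cases, "case1", sub))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
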