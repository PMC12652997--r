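snv_df <- function(classes) {
  tibble::tibble(ref = substr(classes, 1, 1), alt = substr(classes, 3, 3))
}

test_that("Ts/Tv arithmetic matches published and toy values", {
  # shared FFPE SNVs: 3,050,681 transitions / 1,444,558 transversions
  expect_equal(round(3050681 / 1444558, 2), 2.11)
  expect_equal(ts_tv_ratio(snv_df(c("A>G", "C>T", "A>C", "G>T"))), 1.0)
  expect_true(is.na(ts_tv_ratio(snv_df("A>G"))))
  expect_error(ts_tv_ratio(tibble::tibble(ref = "AT", alt = "A")), "SNV")
})

test_that("del/ins arithmetic matches published and toy values", {
  shared_ff <- tibble::tibble(
    ref = c(rep("AT", 2), rep("A", 2)),
    alt = c(rep("A", 2), rep("AT", 2))
  )
  expect_equal(del_ins_ratio(shared_ff), 1.0)
  expect_equal(round(937206 / 898956, 2), 1.04)
  expect_equal(round(113243 / 149605, 2), 0.76)
  expect_true(is.na(del_ins_ratio(
    tibble::tibble(ref = "AT", alt = "A")[0, ]
  )))
  expect_error(del_ins_ratio(tibble::tibble(ref = "A", alt = "G")),
               "insertion/deletion")
})

test_that("het/hom ratios and their mean follow the definitions", {
  cs <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:15, ref = "A", alt = "G"),
    list(S1 = c(rep("0/1", 10), rep("1/1", 5)))
  )
  expect_equal(het_hom_ratio(cs, "S1"), 2.0)
  cs2 <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:4, ref = "A", alt = "G"),
    list(a = c("0/1", "1/1", "0/0", "0/0"),   # 1 het / 1 hom = 1
         b = c("0/1", "0/1", "1/1", "0/0"),   # 2/1 = 2
         c = c("0/1", "0/1", "0/1", "1/1"))   # 3/1 = 3
  )
  expect_equal(het_hom_table(cs2)$het_hom, c(1, 2, 3))
  expect_equal(mean_het_hom(cs2), 2.0)
  cs3 <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1L, ref = "A", alt = "G"),
    list(S1 = "0/1")
  )
  expect_true(is.na(het_hom_ratio(cs3, "S1")))
})

test_that("singletons are keys carried by exactly one sample", {
  # 6 keys; carrier counts per position: 3, 1, 2, 2, 1, 2
  cs <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:6, ref = "A", alt = "G"),
    list(
      s1 = c("0/1", "0/1", "0/0", "1/1", "0/0", "0/1"),
      s2 = c("0/1", "0/0", "0/1", "1/1", "1/1", "0/1"),
      s3 = c("0/1", "0/0", "0/1", "0/0", "0/0", "./.")
    )
  )
  expect_equal(singleton_count(cs), 2)
  # a single-sample call set: every carried key is a singleton
  one <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:3, ref = "A", alt = "G"),
    list(S = c("0/1", "1/1", "0/0"))
  )
  expect_equal(singleton_count(one), 2)
  # key het in 2 of 3 samples is not a singleton
  two <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1L, ref = "A", alt = "G"),
    list(a = "0/1", b = "0/1", c = "0/0")
  )
  expect_equal(singleton_count(two), 0)
})

test_that("multiallelic sites count distinct decomposed origins", {
  plain <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:4, ref = "A", alt = "G"),
    list(S = rep("0/1", 4))
  )
  expect_equal(multiallelic_site_count(plain), 0)
  df <- tibble::tibble(
    contig = "chr1", pos = c(1L, 1L, 2L, 3L, 3L, 4L),
    ref = "A", alt = c("G", "T", "G", "G", "C", "G"),
    multiallelic_origin = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
    gt_S = "0/1"
  )
  expect_equal(multiallelic_site_count(call_set(df)), 2)
})

test_that("substitution spectrum scales counts to per-10Mb rates", {
  cs <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:400, ref = "C", alt = "T"),
    list(S = rep("0/1", 400))
  )
  sp <- substitution_spectrum(cs, "S", genome_size = 4e7)
  ct <- sp[sp$class == "C>T", ]
  expect_equal(ct$count, 400)
  expect_equal(ct$rate_per_10mb, 100)
  expect_equal(ct$poisson_se, 5)
  # empty classes have rate 0 and se 0
  expect_true(all(sp$rate_per_10mb[sp$class != "C>T"] == 0))
  expect_true(all(sp$poisson_se[sp$class != "C>T"] == 0))
})

test_that("one call in each class at 10 Mb gives unit rates and SEs", {
  classes <- substitution_classes()
  cs <- toy_callset(
    tibble::tibble(contig = "chr1", pos = seq_along(classes),
                   ref = substr(classes, 1, 1),
                   alt = substr(classes, 3, 3)),
    list(S = rep("1/1", 12))
  )
  sp <- substitution_spectrum(cs, "S", genome_size = 1e7)
  expect_equal(sp$rate_per_10mb, rep(1, 12))
  expect_equal(sp$poisson_se, rep(1, 12))
  expect_equal(sum(sp$count), 12)
})

test_that("spectrum counts sum to the SNV count and scale with genome", {
  g <- genome_model()
  cs <- generate_truth(g, truth_params(seed = 31, n_snv = 2000,
                                       n_indel = 500))
  sp1 <- substitution_spectrum(cs, "S1", genome_size = 1e7)
  carried <- sum(genotype_class(cs$gt_S1) %in% c("het", "hom_alt") &
                   classify_allele(cs$ref, cs$alt) == "snv")
  expect_equal(sum(sp1$count), carried)
  sp2 <- substitution_spectrum(cs, "S1", genome_size = 2e7)
  expect_equal(sp2$rate_per_10mb, sp1$rate_per_10mb / 2)
  expect_equal(sp2$poisson_se, sp1$poisson_se / 2)
})

test_that("spectrum-based Ts/Tv agrees with ts_tv_ratio", {
  g <- genome_model()
  cs <- generate_truth(g, truth_params(seed = 32, n_snv = 3000,
                                       n_indel = 0, n_samples = 1))
  sp <- substitution_spectrum(cs, "S1", genome_size = 1e7)
  ts <- sum(sp$count[sp$class %in% c("A>G", "G>A", "C>T", "T>C")])
  tv <- sum(sp$count) - ts
  carried <- cs_sub <- tibble::as_tibble(cs)[
    genotype_class(cs$gt_S1) %in% c("het", "hom_alt"), ]
  expect_equal(ts / tv, ts_tv_ratio(carried))
})

test_that("spectrum contrasts detect identical and doubled classes", {
  cs <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:100, ref = "C", alt = "T"),
    list(S = rep("0/1", 100))
  )
  a <- substitution_spectrum(cs, "S", genome_size = 1e7)
  same <- spectrum_contrast(a, a)
  expect_true(all(same$rate_diff == 0))
  expect_equal(same$rate_ratio[same$class == "C>T"], 1)
  doubled <- toy_callset(
    tibble::tibble(contig = "chr1", pos = 1:200, ref = "C", alt = "T"),
    list(S = rep("0/1", 200))
  )
  b <- substitution_spectrum(doubled, "S", genome_size = 1e7)
  ctr <- spectrum_contrast(a, b)
  expect_equal(ctr$rate_ratio[ctr$class == "C>T"], 2)
  expect_true(all(is.na(ctr$rate_ratio[ctr$class != "C>T"])))
  bad <- substitution_spectrum(cs, "S", genome_size = 2e7)
  expect_error(spectrum_contrast(a, bad), "genome size")
})

test_that("call-set summary assembles internally consistent counts", {
  g <- genome_model()
  cs <- generate_truth(g, truth_params(seed = 33, n_snv = 1000,
                                       n_indel = 400,
                                       multiallelic_fraction = 0.02))
  s <- callset_summary(cs)
  expect_equal(s$ts + s$tv, s$n_snv)
  expect_equal(s$n_del + s$n_ins, s$n_indel)
  expect_equal(s$n_snv + s$n_indel + s$n_mnv, s$n_records)
  expect_gt(s$n_multiallelic_sites, 0)
  expect_equal(s, glance(cs))
})
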