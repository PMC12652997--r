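# SE helpers for simulation-recovery checks: ratio estimators are checked
# on the proportion scale (delta method) at 3 standard errors.
ratio_tol <- function(target, n, k = 3) {
  p <- target / (1 + target)
  k * sqrt(p * (1 - p) / n) / (1 - p)^2
}

test_that("generation is fully deterministic under a fixed seed", {
  g <- genome_model()
  p <- truth_params(seed = 101, n_snv = 500, n_indel = 200)
  expect_identical(generate_truth(g, p), generate_truth(g, p))
  truth <- generate_truth(g, p)
  cp <- caller_profile(seed = 102, fn_rate = 0.1, fp_rate = 0.1)
  expect_identical(simulate_caller(truth, cp, g),
                   simulate_caller(truth, cp, g))
  expect_identical(generate_cohort(g, 10, n_background = 100, seed = 103),
                   generate_cohort(g, 10, n_background = 100, seed = 103))
})

test_that("zero requested variants give an empty call set", {
  g <- genome_model()
  empty <- generate_truth(g, truth_params(seed = 1, n_snv = 0,
                                          n_indel = 0))
  expect_equal(nrow(empty), 0)
  expect_equal(call_set_samples(empty), c("S1", "S2", "S3"))
})

test_that("more variants than genome positions is an error", {
  tiny <- genome_model(tibble::tibble(name = "c1", length = 50,
                                      role = "autosome"))
  expect_error(
    generate_truth(tiny, truth_params(seed = 1, n_snv = 100,
                                      n_indel = 0)),
    "More variants"
  )
})

test_that("generated truth hits its target ratios within sampling error", {
  g <- genome_model()
  n_snv <- 30000
  truth <- generate_truth(g, truth_params(seed = 104, n_snv = n_snv,
                                          n_indel = 12000))
  cls <- classify_allele(truth$ref, truth$alt)
  snv <- tibble::as_tibble(truth)[cls == "snv", ]
  expect_equal(ts_tv_ratio(snv), 2.1,
               tolerance = ratio_tol(2.1, n_snv) / 2.1)
  indel <- tibble::as_tibble(truth)[cls != "snv", ]
  expect_equal(del_ins_ratio(indel), 1.04,
               tolerance = ratio_tol(1.04, 12000) / 1.04)
  # per-sample het/hom, expectation 2*beta/(alpha+1) = target
  hh <- het_hom_table(truth)
  expect_true(all(abs(hh$het_hom - 1.35) < 0.1))
  # positions unique per (contig, pos, alt); multiallelic flag consistent
  expect_equal(anyDuplicated(paste(truth$contig, truth$pos, truth$alt)),
               0)
})

test_that("the het/hom calibration closed form is correct by simulation", {
  expect_equal(calibrate_het_hom(1.35, alpha = 1), 1.35)
  expect_equal(calibrate_het_hom(2, alpha = 3), 4)
  withr::with_seed(9, {
    p <- rbeta(2e5, 1, calibrate_het_hom(1.35, alpha = 1))
    het <- 2 * p * (1 - p)
    hom <- p^2
    expect_equal(mean(het) / mean(hom), 1.35, tolerance = 0.02)
  })
})

test_that("a perfect caller reproduces the truth exactly", {
  g <- genome_model()
  truth <- generate_truth(g, truth_params(seed = 105, n_snv = 400,
                                          n_indel = 100))
  q <- simulate_caller(truth, caller_profile(seed = 106, fn_rate = 0,
                                             fp_rate = 0,
                                             genotype_error_rate = 0), g)
  cc <- compare_sample(truth, q, "S1")
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$concordant, cc$tp)
})

test_that("configured caller error rates are recovered by benchmarking", {
  g <- genome_model()
  n <- 30000
  truth <- generate_truth(g, truth_params(seed = 107, n_snv = n,
                                          n_indel = 0))
  fn <- 0.05
  ge <- 0.02
  fpr <- 0.06
  q <- simulate_caller(truth, caller_profile(seed = 108, fn_rate = fn,
                                             fp_rate = fpr,
                                             genotype_error_rate = ge), g)
  cc <- compare_sample(truth, q, "S2")
  # recall ~ 1 - fn within 3 binomial SE
  se_rec <- sqrt(fn * (1 - fn) / cc$truth_total)
  expect_lt(abs(cc$tp / cc$truth_total - (1 - fn)), 3 * se_rec)
  # genotype concordance ~ 1 - ge within 3 binomial SE
  se_ge <- sqrt(ge * (1 - ge) / cc$tp)
  expect_lt(abs(cc$concordant / cc$tp - (1 - ge)), 3 * se_ge)
  # false calls ~ Poisson(fpr * n) within 3 SE
  expect_lt(abs(cc$fp - fpr * n), 3 * sqrt(fpr * n))
})

test_that("injected deamination enrichment is recovered by contrast", {
  g <- genome_model()
  truth <- generate_truth(g, truth_params(seed = 109, n_snv = 20000,
                                          n_indel = 0))
  m <- 5
  ffpe <- inject_ffpe_artifacts(
    truth, ffpe_artifact_profile(seed = 110, deamination_multiplier = m,
                                 extra_fp_rate = 0), g)
  a <- substitution_spectrum(truth, NULL, genome_size(g))
  b <- substitution_spectrum(ffpe, NULL, genome_size(g))
  ctr <- spectrum_contrast(a, b)
  deam <- ctr$class %in% c("C>T", "G>A")
  for (i in which(deam)) {
    se <- sqrt(ctr$count_b[i]) / ctr$count_a[i]
    expect_lt(abs(ctr$rate_ratio[i] - m), 3 * se)
  }
  expect_true(all(ctr$rate_ratio[!deam] == 1))
  # multiplier 1 with no extras changes nothing
  same <- inject_ffpe_artifacts(
    truth, ffpe_artifact_profile(seed = 111, deamination_multiplier = 1,
                                 extra_fp_rate = 0), g)
  expect_identical(tibble::as_tibble(same), tibble::as_tibble(truth))
})

test_that("cohorts separate cases, controls and the planted variant", {
  g <- genome_model()
  coh <- generate_cohort(g, n_controls = 40, seed = 112)
  expect_equal(call_set_samples(coh$cases),
               c("case1", "case2", "case3"))
  expect_equal(length(call_set_samples(coh$controls)), 40)
  planted_in_cases <- dplyr::inner_join(
    tibble::as_tibble(coh$cases), coh$planted,
    by = c("contig", "pos", "ref", "alt")
  )
  expect_equal(nrow(planted_in_cases), 1)
  expect_equal(planted_in_cases$impact, "HIGH")
  expect_true(all(genotype_class(
    unlist(planted_in_cases[paste0("gt_", call_set_samples(coh$cases))])
  ) == "hom_alt"))
  # the planted key is absent from the control call set
  expect_equal(nrow(dplyr::inner_join(
    tibble::as_tibble(coh$controls), coh$planted,
    by = c("contig", "pos", "ref", "alt")
  )), 0)
  expect_error(generate_cohort(g, n_controls = -1, seed = 1), ">= 0")
})

test_that("generated call sets round-trip through VCF with no loss", {
  g <- genome_model()
  truth <- generate_truth(g, truth_params(seed = 113, n_snv = 250,
                                          n_indel = 80,
                                          multiallelic_fraction = 0.03))
  path <- tempfile(fileext = ".vcf")
  write_vcf(truth, path, genome = g)
  back <- read_vcf(path)
  expect_equal(nrow(back), nrow(truth))
  expect_setequal(
    paste(back$contig, back$pos, back$ref, back$alt),
    paste(truth$contig, truth$pos, truth$ref, truth$alt)
  )
})
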