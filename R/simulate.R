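# Seeded synthetic call-set generators. They emulate the statistical
# structure the analysis layer assumes -- a multi-sample germline truth set
# with realistic Ts/Tv, het/hom and del/ins ratios, imperfect callers with
# configurable miss/false-call/genotype-error rates, FFPE deamination
# artifacts, and a case/control cohort with a planted recessive causal
# variant -- without any reference FASTA: positions are abstract
# coordinates on a toy genome model and reference bases are drawn
# uniformly, consistent only within a record.

#' Toy genome model
#'
#' An ordered contig table with autosome/sex/unplaced labels. The default
#' model has five 10-Mb autosomes, one 10-Mb X chromosome and one 10-Mb
#' unplaced scaffold: large enough for stable ratio estimates at
#' 10^5 variants, small enough for seconds-scale simulation.
#'
#' @param contigs Optional data frame with columns `name`, `length`,
#'   `role` (one of `"autosome"`, `"sex"`, `"unplaced"`).
#' @return A `genome_model` tibble.
#' @export
genome_model <- function(contigs = NULL) {
  x <- contigs %||% tibble(
    name = c(paste0("chr", 1:5), "chrX", "chrUn_scaffold1"),
    length = 1e7,
    role = c(rep("autosome", 5), "sex", "unplaced")
  )
  x <- as_tibble(x)[c("name", "length", "role")]
  x$name <- as.character(x$name)
  x$length <- as.numeric(x$length)
  if (anyDuplicated(x$name)) abort("Contig names must be unique.")
  if (any(x$length < 1)) abort("Contig lengths must be >= 1.")
  if (!all(x$role %in% c("autosome", "sex", "unplaced"))) {
    abort("Contig roles must be autosome, sex or unplaced.")
  }
  structure(x, class = c("genome_model", class(x)))
}

#' @rdname genome_model
#' @param g A `genome_model`.
#' @return For `genome_size()`: total bp; for `autosome_names()`: the
#'   autosomal contig names.
#' @export
genome_size <- function(g) sum(g$length)

#' @rdname genome_model
#' @export
autosome_names <- function(g) g$name[g$role == "autosome"]

#' Calibrate the allele-frequency prior to a target het/hom ratio
#'
#' Genotypes are drawn per site under Hardy-Weinberg equilibrium with an
#' alternate-allele frequency p ~ Beta(alpha, beta). A sample is then het
#' with probability 2p(1-p) and hom-alt with probability p^2, so the
#' expected per-sample het/hom-alt count ratio is
#' `2 E[p(1-p)] / E[p^2] = 2*beta / (alpha + 1)`, independent of the
#' number of sites. Inverting gives the `beta` shape that hits a target
#' ratio for a chosen `alpha`.
#'
#' @param target Target per-sample het/hom-alt ratio.
#' @param alpha Beta-distribution shape for the alternate allele (default
#'   1: a flat site-frequency profile).
#' @return The calibrated `beta` shape.
#' @export
#' @examples
#' calibrate_het_hom(1.35) # beta shape for the het/hom of a germline set
calibrate_het_hom <- function(target, alpha = 1) {
  if (!is.numeric(target) || target <= 0) abort("`target` must be > 0.")
  target * (alpha + 1) / 2
}

#' Truth-set generator parameters
#'
#' Defaults are the study conditions the package emulates: a germline
#' truth set with Ts/Tv 2.1, per-sample het/hom 1.35 and del/ins 1.04,
#' three samples, and a multiallelic-site fraction of 0.001 (the order
#' observed in caller-concordant whole-genome call sets).
#'
#' @param seed Mandatory integer seed; all randomness derives from it.
#' @param n_snv,n_indel Numbers of SNV and indel records.
#' @param target_ts_tv,target_het_hom,target_del_ins Target ratios (in
#'   expectation).
#' @param multiallelic_fraction Fraction of SNV sites carrying a second
#'   alternate allele.
#' @param n_samples Number of samples.
#' @param af_alpha Beta shape `alpha` of the allele-frequency prior; the
#'   `beta` shape is set by [calibrate_het_hom()].
#' @param annotation_fail_fraction Fraction of records given one
#'   hard-filter-violating site annotation (for filter testing).
#' @param impact_probs Optional named probabilities over
#'   HIGH/MODERATE/LOW/MODIFIER for impact annotations (`NULL`: none).
#' @return A `truth_params` object.
#' @export
truth_params <- function(seed, n_snv = 50000, n_indel = 19000,
                         target_ts_tv = 2.1, target_het_hom = 1.35,
                         target_del_ins = 1.04,
                         multiallelic_fraction = 0.001, n_samples = 3,
                         af_alpha = 1, annotation_fail_fraction = 0,
                         impact_probs = NULL) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  if (n_snv < 0 || n_indel < 0) abort("Variant counts must be >= 0.")
  if (target_ts_tv <= 0 || target_het_hom <= 0 || target_del_ins <= 0) {
    abort("Target ratios must be > 0.")
  }
  if (multiallelic_fraction < 0 || multiallelic_fraction > 1 ||
      annotation_fail_fraction < 0 || annotation_fail_fraction > 1) {
    abort("Fractions must be in [0, 1].")
  }
  structure(
    list(seed = as.integer(seed), n_snv = as.integer(n_snv),
         n_indel = as.integer(n_indel), target_ts_tv = target_ts_tv,
         target_het_hom = target_het_hom, target_del_ins = target_del_ins,
         multiallelic_fraction = multiallelic_fraction,
         n_samples = as.integer(n_samples), af_alpha = af_alpha,
         annotation_fail_fraction = annotation_fail_fraction,
         impact_probs = impact_probs),
    class = "truth_params"
  )
}

#' Caller error profile
#'
#' The error model of an imperfect variant caller: each truth record is
#' missed with probability `fn_rate` (record-level, affecting all
#' samples), each surviving non-reference genotype is corrupted (het and
#' hom-alt swapped) with probability `genotype_error_rate`, and false
#' calls are added at fresh positions at an expected `fp_rate` per truth
#' record, with an SNV Ts/Tv of `fp_ts_tv` (about 1 for random artifacts,
#' versus about 2.1 for genuine germline variation -- the signature that
#' makes caller-unique call sets look artifact-enriched). Defaults are
#' calibrated to the FF-tissue caller-vs-caller agreement scale: 4% misses,
#' 4% false calls, 1% genotype errors.
#'
#' @param seed Mandatory integer seed.
#' @param fn_rate Per-record miss probability.
#' @param fp_rate Expected false calls per truth record.
#' @param genotype_error_rate Probability a recovered non-reference
#'   genotype class is corrupted.
#' @param fp_ts_tv Ts/Tv ratio of false SNV calls.
#' @return A `caller_profile` object.
#' @export
caller_profile <- function(seed, fn_rate = 0.04, fp_rate = 0.04,
                           genotype_error_rate = 0.01, fp_ts_tv = 1.0) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  for (p in c(fn_rate, genotype_error_rate)) {
    if (p < 0 || p > 1) abort("Probabilities must be in [0, 1].")
  }
  if (fp_rate < 0) abort("`fp_rate` must be >= 0.")
  if (fp_ts_tv <= 0) abort("`fp_ts_tv` must be > 0.")
  structure(
    list(seed = as.integer(seed), fn_rate = fn_rate, fp_rate = fp_rate,
         genotype_error_rate = genotype_error_rate, fp_ts_tv = fp_ts_tv),
    class = "caller_profile"
  )
}

#' FFPE artifact profile
#'
#' Formalin fixation deaminates cytosine (and 5-methylcytosine), creating
#' dU:G and T:G mismatches that surface as artifactual C>T and G>A calls.
#' `deamination_multiplier` is the factor by which the cohort-mean C>T and
#' G>A call rates of the injected set exceed the matched clean call set
#' (1.2 emulates the 15-20% transition inflation seen in permissively
#' filtered FFPE calls); `extra_fp_rate` adds class-proportional
#' background false calls on top (all twelve classes inflated equally).
#'
#' @param seed Mandatory integer seed.
#' @param deamination_multiplier Target C>T / G>A rate multiplier (>= 1).
#' @param extra_fp_rate Expected class-proportional extra false calls, as
#'   a fraction of the baseline class rate.
#' @return An `ffpe_artifact_profile` object.
#' @export
ffpe_artifact_profile <- function(seed, deamination_multiplier = 1.2,
                                  extra_fp_rate = 0.05) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  if (deamination_multiplier < 1) {
    abort("`deamination_multiplier` must be >= 1.")
  }
  if (extra_fp_rate < 0) abort("`extra_fp_rate` must be >= 0.")
  structure(
    list(seed = as.integer(seed),
         deamination_multiplier = deamination_multiplier,
         extra_fp_rate = extra_fp_rate),
    class = "ffpe_artifact_profile"
  )
}

# ---- internal drawing helpers (RNG assumed seeded by the caller) --------

# unique genome-wide offsets, optionally avoiding an exclusion set
draw_offsets <- function(g, n, exclude = numeric(0)) {
  gs <- genome_size(g)
  if (n + length(exclude) > gs) {
    abort("More variants requested than available positions.")
  }
  off <- numeric(0)
  while (length(off) < n) {
    need <- n - length(off)
    cand <- sample.int(gs, min(gs, ceiling(need * 1.2) + 10L))
    cand <- setdiff(cand, c(off, exclude))
    off <- c(off, cand[seq_len(min(need, length(cand)))])
  }
  off
}

offsets_to_positions <- function(g, off) {
  ends <- cumsum(g$length)
  starts <- ends - g$length
  ci <- findInterval(off - 1, ends) + 1L
  tibble(contig = g$name[ci], pos = as.integer(off - starts[ci]))
}

positions_to_offsets <- function(g, contig, pos) {
  ends <- cumsum(g$length)
  starts <- setNames(ends - g$length, g$name)
  starts[contig] + pos
}

TV_PARTNER_1 <- c(A = "C", G = "C", C = "A", T = "A")
TV_PARTNER_2 <- c(A = "T", G = "T", C = "G", T = "G")

# alternate allele for given reference bases at a target Ts/Tv
draw_alt_given_ref <- function(ref, ts_tv) {
  n <- length(ref)
  alt <- character(n)
  is_ts <- runif(n) < ts_tv / (1 + ts_tv)
  alt[is_ts] <- TRANSITION_PARTNER[ref[is_ts]]
  first <- runif(n) < 0.5
  alt[!is_ts & first] <- TV_PARTNER_1[ref[!is_ts & first]]
  alt[!is_ts & !first] <- TV_PARTNER_2[ref[!is_ts & !first]]
  alt
}

draw_snv_alleles <- function(n, ts_tv) {
  if (n == 0) return(tibble(ref = character(0), alt = character(0)))
  ref <- sample(DNA_BASES, n, replace = TRUE)
  tibble(ref = ref, alt = draw_alt_given_ref(ref, ts_tv))
}

draw_indel_alleles <- function(n, del_ins) {
  if (n == 0) return(tibble(ref = character(0), alt = character(0)))
  is_del <- runif(n) < del_ins / (1 + del_ins)
  len <- sample(1:3, n, replace = TRUE)
  anchor <- sample(DNA_BASES, n, replace = TRUE)
  extra <- vapply(len, function(k) {
    paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
  }, character(1))
  tibble(
    ref = ifelse(is_del, paste0(anchor, extra), anchor),
    alt = ifelse(is_del, anchor, paste0(anchor, extra))
  )
}

# Hardy-Weinberg genotype strings, redrawing sites with no carrier
draw_gt_matrix <- function(n_sites, n_samples, alpha, beta) {
  if (n_sites == 0 || n_samples == 0) {
    return(matrix(character(0), nrow = n_sites, ncol = n_samples))
  }
  draw <- function(k) {
    p <- rbeta(k, alpha, beta)
    matrix(rbinom(k * n_samples, 2L, rep(p, n_samples)), nrow = k)
  }
  counts <- draw(n_sites)
  repeat {
    bad <- which(rowSums(counts) == 0L)
    if (length(bad) == 0) break
    counts[bad, ] <- draw(length(bad))
  }
  matrix(c("0/0", "0/1", "1/1")[counts + 1L], nrow = n_sites)
}

# site annotations drawn from a passing mixture, with a configurable
# fraction given one criterion-violating value
draw_annotations <- function(n, cls, fail_fraction = 0) {
  out <- tibble(
    qual = runif(n, 100, 2000),
    QD = runif(n, 10, 35),
    SOR = runif(n, 0.3, 2.5),
    FS = runif(n, 0, 20),
    MQ = runif(n, 50, 60),
    MQRankSum = runif(n, -3, 3),
    ReadPosRankSum = runif(n, -3, 3)
  )
  for (i in which(runif(n) < fail_fraction)) {
    is_snv <- cls[i] %in% c("snv", "mnv")
    crit <- if (is_snv) {
      c("QD", "QUAL", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
    } else {
      c("QD", "QUAL", "SOR", "FS", "ReadPosRankSum")
    }
    switch(sample(crit, 1L),
      QD = out$QD[i] <- runif(1, 0, 1.9),
      QUAL = out$qual[i] <- runif(1, 1, 29),
      SOR = out$SOR[i] <- if (is_snv) runif(1, 3.1, 6) else
        runif(1, 10.1, 15),
      FS = out$FS[i] <- if (is_snv) runif(1, 60.1, 120) else
        runif(1, 200.1, 300),
      MQ = out$MQ[i] <- runif(1, 10, 39.9),
      MQRankSum = out$MQRankSum[i] <- runif(1, -20, -12.6),
      ReadPosRankSum = out$ReadPosRankSum[i] <- if (is_snv)
        runif(1, -15, -8.1) else runif(1, -25, -20.1)
    )
  }
  out
}

draw_impacts <- function(n, impact_probs) {
  if (is.null(impact_probs)) return(rep(NA_character_, n))
  sample(names(impact_probs), n, replace = TRUE, prob = impact_probs)
}

# ---- generators ---------------------------------------------------------

#' Generate a synthetic germline truth set
#'
#' Draws `n_snv + n_indel` allele-level records at unique genome positions.
#' Substitution classes are drawn so the expected Ts/Tv hits
#' `target_ts_tv`, indels so del/ins hits `target_del_ins`, and genotypes
#' under per-site Hardy-Weinberg with a Beta allele-frequency prior
#' calibrated so each sample's expected het/hom-alt ratio is
#' `target_het_hom`. Sites where no sample carries the alternate allele
#' are redrawn (a call set only contains called sites; the redraw leaves
#' per-sample het/hom ratios untouched). A `multiallelic_fraction` of SNV
#' sites receive a second alternate allele; both of their records are
#' flagged `multiallelic_origin`. The same seed reproduces the call set
#' exactly.
#'
#' @param genome A [genome_model()].
#' @param params A [truth_params()] object.
#' @return A [call_set()] with samples `S1..Sn`.
#' @export
generate_truth <- function(genome, params) {
  if (!inherits(params, "truth_params")) {
    abort("`params` must be created by truth_params().")
  }
  withr::with_seed(params$seed, {
    n_ma <- round(params$n_snv * params$multiallelic_fraction /
                    (1 + params$multiallelic_fraction))
    s <- params$n_snv - n_ma
    n_sites <- s + params$n_indel
    samples <- paste0("S", seq_len(params$n_samples))
    if (n_sites + n_ma == 0) {
      empty <- tibble(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0))
      for (smp in samples) empty[[paste0("gt_", smp)]] <- character(0)
      return(call_set(empty, provenance = "synthetic_truth"))
    }
    posd <- offsets_to_positions(genome, draw_offsets(genome, n_sites))
    snv <- draw_snv_alleles(s, params$target_ts_tv)
    indel <- draw_indel_alleles(params$n_indel, params$target_del_ins)
    rec <- tibble(
      contig = posd$contig,
      pos = posd$pos,
      ref = c(snv$ref, indel$ref),
      alt = c(snv$alt, indel$alt),
      multiallelic_origin = FALSE
    )
    if (n_ma > 0) {
      ma_idx <- sample.int(s, n_ma)
      alt2 <- draw_alt_given_ref(rec$ref[ma_idx], params$target_ts_tv)
      clash <- alt2 == rec$alt[ma_idx]
      while (any(clash)) {
        alt2[clash] <- draw_alt_given_ref(rec$ref[ma_idx][clash],
                                          params$target_ts_tv)
        clash <- alt2 == rec$alt[ma_idx]
      }
      second <- rec[ma_idx, ]
      second$alt <- alt2
      rec$multiallelic_origin[ma_idx] <- TRUE
      second$multiallelic_origin <- TRUE
      rec <- bind_rows(rec, second)
    }
    n <- nrow(rec)
    cls <- classify_allele(rec$ref, rec$alt)
    beta <- calibrate_het_hom(params$target_het_hom, params$af_alpha)
    gt <- draw_gt_matrix(n, params$n_samples, params$af_alpha, beta)
    ann <- draw_annotations(n, cls, params$annotation_fail_fraction)
    rec <- bind_cols(rec, ann)
    rec$impact <- draw_impacts(n, params$impact_probs)
    for (j in seq_along(samples)) {
      rec[[paste0("gt_", samples[j])]] <- gt[, j]
    }
    call_set(rec, provenance = "synthetic_truth")
  })
}

#' Simulate an imperfect caller on a truth set
#'
#' Applies a [caller_profile()] to a truth call set: records are dropped
#' with probability `fn_rate`, surviving non-reference genotypes corrupted
#' (het/hom-alt swapped) with probability `genotype_error_rate` per sample,
#' and `Poisson(fp_rate * n_truth)` false records added at fresh positions.
#' False SNVs follow the profile's `fp_ts_tv` class mix, false indels a
#' balanced del/ins mix, in proportion to the truth set's SNV/indel split;
#' false records are heterozygous in every sample (matching the extreme
#' het/hom ratios of caller-unique call sets). False positions never
#' collide with truth positions.
#'
#' @param truth A truth [call_set()].
#' @param profile A [caller_profile()].
#' @param genome The [genome_model()] the truth set was generated on.
#' @return A [call_set()] with the same samples.
#' @export
simulate_caller <- function(truth, profile, genome) {
  if (!inherits(profile, "caller_profile")) {
    abort("`profile` must be created by caller_profile().")
  }
  withr::with_seed(profile$seed, {
    n <- nrow(as_tibble(truth))
    samples <- call_set_samples(truth)
    keep <- runif(n) >= profile$fn_rate
    rec <- as_tibble(truth)[keep, , drop = FALSE]
    for (smp in samples) {
      col <- paste0("gt_", smp)
      cls <- genotype_class(rec[[col]])
      flip <- cls %in% c("het", "hom_alt") &
        runif(nrow(rec)) < profile$genotype_error_rate
      rec[[col]][flip] <- ifelse(cls[flip] == "het", "1/1", "0/1")
    }
    n_fp <- rpois(1, profile$fp_rate * n)
    if (n_fp > 0) {
      truth_cls <- classify_allele(truth$ref, truth$alt)
      p_snv <- if (n == 0) 1 else mean(truth_cls == "snv")
      n_fp_snv <- rbinom(1, n_fp, p_snv)
      exclude <- positions_to_offsets(genome, truth$contig, truth$pos)
      posd <- offsets_to_positions(genome,
                                   draw_offsets(genome, n_fp, exclude))
      alleles <- bind_rows(
        draw_snv_alleles(n_fp_snv, profile$fp_ts_tv),
        draw_indel_alleles(n_fp - n_fp_snv, 1.0)
      )
      fp <- tibble(
        contig = posd$contig, pos = posd$pos,
        ref = alleles$ref, alt = alleles$alt,
        multiallelic_origin = FALSE
      )
      fp <- bind_cols(
        fp,
        draw_annotations(n_fp, classify_allele(fp$ref, fp$alt))
      )
      for (smp in samples) fp[[paste0("gt_", smp)]] <- "0/1"
      rec <- bind_rows(rec, fp)
    }
    call_set(rec, provenance = paste0(
      attr(truth, "provenance") %||% "truth", "+simulated_caller"
    ))
  })
}

#' Inject FFPE deamination artifacts into a call set
#'
#' Adds false SNV records at fresh positions so that, relative to the
#' input, the cohort-mean C>T and G>A call rates are multiplied by
#' `deamination_multiplier` (in expectation) while `extra_fp_rate` adds
#' class-proportional background false calls to all twelve classes.
#' Artifact records are heterozygous in every sample.
#'
#' @param query A [call_set()] (the clean caller output).
#' @param profile An [ffpe_artifact_profile()].
#' @param genome The [genome_model()] the call set lives on.
#' @return A [call_set()] with artifacts appended.
#' @export
inject_ffpe_artifacts <- function(query, profile, genome) {
  if (!inherits(profile, "ffpe_artifact_profile")) {
    abort("`profile` must be created by ffpe_artifact_profile().")
  }
  withr::with_seed(profile$seed, {
    classes <- substitution_classes()
    base <- substitution_spectrum(query, sample = NULL,
                                  genome_size = genome_size(genome))
    is_deam <- classes %in% c("C>T", "G>A")
    lambda <- base$count * (profile$extra_fp_rate +
                              ifelse(is_deam,
                                     profile$deamination_multiplier - 1, 0))
    extra <- rpois(length(classes), lambda)
    n_extra <- sum(extra)
    if (n_extra == 0) return(query)
    ref <- rep(substr(classes, 1, 1), extra)
    alt <- rep(substr(classes, 3, 3), extra)
    exclude <- positions_to_offsets(genome, query$contig, query$pos)
    posd <- offsets_to_positions(genome,
                                 draw_offsets(genome, n_extra, exclude))
    art <- tibble(contig = posd$contig, pos = posd$pos,
                  ref = ref, alt = alt, multiallelic_origin = FALSE)
    art <- bind_cols(art, draw_annotations(n_extra, rep("snv", n_extra)))
    for (smp in call_set_samples(query)) art[[paste0("gt_", smp)]] <- "0/1"
    call_set(
      bind_rows(as_tibble(query), art),
      provenance = paste0(attr(query, "provenance") %||% "query",
                          "+ffpe_artifacts")
    )
  })
}

#' Default critical interval for a genome model
#'
#' A stand-in for a linkage/autozygosity-mapped critical interval: one
#' segment on each of (up to) five autosomes, each spanning `fraction` of
#' its contig starting at 40% of the contig length. With the default
#' genome model this yields 5 segments of 0.25 Mb (1.25 Mb, ~1.8% of the
#' genome), mirroring the few-segments-on-few-chromosomes structure of
#' mapped intervals at toy scale.
#'
#' @param genome A [genome_model()].
#' @param n_segments Number of autosomal segments.
#' @param fraction Fraction of each contig covered.
#' @return An [interval_set()].
#' @export
default_critical_interval <- function(genome, n_segments = 5,
                                      fraction = 0.025) {
  auto <- genome[genome$role == "autosome", ]
  auto <- auto[seq_len(min(n_segments, nrow(auto))), ]
  interval_set(tibble(
    contig = auto$name,
    start = as.integer(floor(auto$length * 0.4)) + 1L,
    end = as.integer(floor(auto$length * 0.4) +
                       ceiling(auto$length * fraction))
  ))
}

#' Generate a case/control cohort with a planted recessive causal variant
#'
#' Draws `n_background` biallelic SNV sites genotyped jointly across cases
#' and controls under Hardy-Weinberg with a Beta allele-frequency prior,
#' attaches impact annotations from a background mixture, and plants one
#' causal variant inside the critical interval: homozygous alternate in
#' every case, homozygous reference (or missing) in every control, impact
#' HIGH. Control genotypes are set missing with probability
#' `missing_rate`, emulating incomplete genotyping in large cohorts. The
#' case call set contains the sites carried by at least one case, the
#' control call set the sites carried by at least one control (so the
#' planted key is absent from it, as a truly private allele would be).
#'
#' @param genome A [genome_model()].
#' @param n_controls Number of control samples (>= 0).
#' @param n_cases Number of affected samples.
#' @param n_background Number of background SNV sites.
#' @param target_het_hom,af_alpha Allele-frequency prior calibration, as in
#'   [truth_params()].
#' @param target_ts_tv Ts/Tv of background (and planted) SNVs.
#' @param impact_probs Named impact mixture for background sites.
#' @param missing_rate Per-genotype missing probability in controls.
#' @param interval Critical [interval_set()] (default:
#'   [default_critical_interval()]).
#' @param seed Mandatory integer seed.
#' @return A list with `cases` and `controls` call sets, `planted` (the
#'   causal allele key as a one-row tibble) and `interval`.
#' @export
generate_cohort <- function(genome, n_controls, n_cases = 3,
                            n_background = 2000, target_het_hom = 1.35,
                            af_alpha = 1, target_ts_tv = 2.1,
                            impact_probs = c(MODIFIER = 0.92, LOW = 0.04,
                                             MODERATE = 0.03, HIGH = 0.01),
                            missing_rate = 0.02, interval = NULL,
                            seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory.")
  if (n_controls < 0) abort("`n_controls` must be >= 0.")
  if (n_cases < 1) abort("At least one case is required.")
  interval <- interval %||% default_critical_interval(genome)
  withr::with_seed(as.integer(seed), {
    case_samples <- paste0("case", seq_len(n_cases))
    ctrl_samples <- if (n_controls > 0) {
      paste0("ctrl", seq_len(n_controls))
    } else {
      character(0)
    }
    # planted causal variant inside the critical interval
    seg <- interval[sample.int(nrow(interval), 1L), ]
    planted_pos <- sample(seq(seg$start, seg$end), 1L)
    planted_ref <- sample(DNA_BASES, 1L)
    planted <- tibble(
      contig = seg$contig, pos = as.integer(planted_pos),
      ref = planted_ref,
      alt = draw_alt_given_ref(planted_ref, target_ts_tv)
    )
    exclude <- positions_to_offsets(genome, planted$contig, planted$pos)
    posd <- offsets_to_positions(
      genome, draw_offsets(genome, n_background, exclude)
    )
    snv <- draw_snv_alleles(n_background, target_ts_tv)
    beta <- calibrate_het_hom(target_het_hom, af_alpha)
    gt <- draw_gt_matrix(n_background, n_cases + n_controls,
                         af_alpha, beta)
    rec <- tibble(contig = posd$contig, pos = posd$pos,
                  ref = snv$ref, alt = snv$alt)
    rec$impact <- draw_impacts(n_background, impact_probs)
    planted$impact <- "HIGH"
    rec <- bind_rows(rec, planted)
    gt <- rbind(gt, c(rep("1/1", n_cases), rep("0/0", n_controls)))
    # control missingness
    if (n_controls > 0 && missing_rate > 0) {
      ctrl_part <- gt[, n_cases + seq_len(n_controls), drop = FALSE]
      ctrl_part[runif(length(ctrl_part)) < missing_rate] <- "./."
      gt[, n_cases + seq_len(n_controls)] <- ctrl_part
    }
    ann <- draw_annotations(nrow(rec), rep("snv", nrow(rec)))
    rec <- bind_cols(rec, ann)
    all_samples <- c(case_samples, ctrl_samples)
    carried <- function(cols) {
      if (length(cols) == 0) return(rep(FALSE, nrow(gt)))
      sub <- gt[, cols, drop = FALSE]
      rowSums(sub == "0/1" | sub == "1/1") > 0
    }
    case_rec <- rec
    for (j in seq_len(n_cases)) {
      case_rec[[paste0("gt_", case_samples[j])]] <- gt[, j]
    }
    cases_cs <- call_set(
      case_rec[carried(seq_len(n_cases)), , drop = FALSE],
      provenance = "synthetic_cases"
    )
    ctrl_rec <- rec
    for (j in seq_len(n_controls)) {
      ctrl_rec[[paste0("gt_", ctrl_samples[j])]] <- gt[, n_cases + j]
    }
    controls_cs <- call_set(
      ctrl_rec[carried(n_cases + seq_len(n_controls)), , drop = FALSE],
      provenance = "synthetic_controls"
    )
    list(cases = cases_cs, controls = controls_cs,
         planted = planted[c("contig", "pos", "ref", "alt")],
         interval = interval)
  })
}
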