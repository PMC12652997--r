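# Pipeline orchestration: each run_* step reads a validated config,
# executes the corresponding analysis on VCF inputs, and writes its report
# in both human (TSV) and machine (JSON) form with identical numbers.
# Reported percentages are rounded to two decimals in the TSV mirrors;
# JSON carries full precision.

#' Assemble and validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) consumed
#' by the `run_*` steps. Recognised fields: `vcf_a`, `vcf_b` (two callers'
#' VCFs for truth-set construction), `truth_vcf`, `query_vcf`
#' (benchmarking and spectra), `case_vcf`, `control_vcf`, `interval_bed`,
#' `autosomes`, `case_samples` (prioritization), `genome_size` (bp, for
#' spectra), `thresholds` (nested `snv`/`indel` lists overriding
#' [filter_thresholds()]), `sample_subset`, `out_dir`, `plot_format`
#' (`"pdf"`, `"png"` or `"svg"`) and `seed`.
#'
#' @param config A named list or path to a YAML file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or YAML path.")
  defaults <- list(out_dir = ".", plot_format = "pdf",
                   thresholds = list(), autosomes = NULL,
                   sample_subset = NULL, seed = NULL)
  cfg <- modifyList(defaults, config)
  cfg$thresholds <- filter_thresholds(
    snv = cfg$thresholds$snv %||% list(),
    indel = cfg$thresholds$indel %||% list()
  )
  structure(cfg, class = "pipeline_config")
}

cfg_path <- function(cfg, field) {
  path <- cfg[[field]]
  if (is.null(path)) {
    abort(paste0("Config field `", field, "` is required for this step."))
  }
  if (!file.exists(path)) {
    abort(paste0("Input file for `", field, "` not found: ", path))
  }
  path
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$out_dir
}

write_report <- function(x, out_dir, stem) {
  tsv <- file.path(out_dir, paste0(stem, ".tsv"))
  json <- file.path(out_dir, paste0(stem, ".json"))
  readr::write_tsv(x, tsv)
  jsonlite::write_json(x, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  c(tsv = tsv, json = json)
}

round_pct <- function(x, digits = 2) round(100 * x, digits)

#' Construct a truth set from two callers' VCFs
#'
#' Reads `vcf_a` and `vcf_b`, partitions their allele keys into shared and
#' caller-unique call sets, writes the three partitions as VCFs and a
#' per-partition characterization summary ([callset_summary()] rows) as
#' TSV + JSON.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced to one).
#' @return Invisibly, a list with the three call sets, the `summary`
#'   tibble and output `paths`.
#' @export
run_truth_set <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- ensure_out_dir(cfg)
  a <- read_vcf(cfg_path(cfg, "vcf_a"), cfg$sample_subset)
  b <- read_vcf(cfg_path(cfg, "vcf_b"), cfg$sample_subset)
  parts <- intersect_callsets(a, b)
  paths <- c(
    shared = file.path(out_dir, "truth_shared.vcf"),
    unique_a = file.path(out_dir, "unique_a.vcf"),
    unique_b = file.path(out_dir, "unique_b.vcf")
  )
  write_vcf(parts$shared, paths[["shared"]])
  write_vcf(parts$unique_a, paths[["unique_a"]])
  write_vcf(parts$unique_b, paths[["unique_b"]])
  summary <- purrr::map_dfr(
    c("unique_a", "unique_b", "shared"),
    function(nm) mutate(callset_summary(parts[[nm]]), partition = nm,
                        .before = 1)
  )
  paths <- c(paths, write_report(summary, out_dir, "truth_set_summary"))
  invisible(c(parts, list(summary = summary, paths = paths)))
}

#' Benchmark a query VCF against a truth VCF
#'
#' Runs [compare_callsets()] per sample and variant class and writes the
#' metrics report (counts plus precision/recall/F1, FN/FP rates and
#' genotype concordance as percentages rounded to two decimals in the
#' TSV; full precision in the JSON).
#'
#' @inheritParams run_truth_set
#' @return Invisibly, a list with the `metrics` tibble and output `paths`.
#' @export
run_benchmark <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- ensure_out_dir(cfg)
  truth <- read_vcf(cfg_path(cfg, "truth_vcf"), cfg$sample_subset)
  query <- read_vcf(cfg_path(cfg, "query_vcf"), cfg$sample_subset)
  metrics <- compare_callsets(truth, query)
  report <- metrics |>
    mutate(across(c("precision", "recall", "f1", "fn_rate", "fp_rate",
                    "genotype_concordance"),
                  round_pct))
  paths <- write_report(report, out_dir, "benchmark_metrics")
  invisible(list(metrics = metrics, paths = paths))
}

#' Substitution spectra of one or two call sets
#'
#' Computes the cohort-mean substitution spectrum of `vcf_a` (and of
#' `vcf_b` when given), writes a tidy per-class table, the per-class
#' contrast when both inputs are present, and a bar plot with Poisson
#' error bars.
#'
#' @inheritParams run_truth_set
#' @return Invisibly, a list with `spectra` (tibble), optional `contrast`
#'   and output `paths`.
#' @export
run_spectrum <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- ensure_out_dir(cfg)
  if (is.null(cfg$genome_size)) {
    abort("Config field `genome_size` (bp) is required for spectra.")
  }
  a <- read_vcf(cfg_path(cfg, "vcf_a"), cfg$sample_subset)
  spec_a <- substitution_spectrum(a, sample = NULL,
                                  genome_size = cfg$genome_size)
  spectra <- mutate(as_tibble(spec_a), callset = "a", .before = 1)
  contrast <- NULL
  plot_obj <- autoplot(spec_a)
  if (!is.null(cfg$vcf_b)) {
    b <- read_vcf(cfg_path(cfg, "vcf_b"), cfg$sample_subset)
    spec_b <- substitution_spectrum(b, sample = NULL,
                                    genome_size = cfg$genome_size)
    spectra <- bind_rows(
      spectra, mutate(as_tibble(spec_b), callset = "b", .before = 1)
    )
    contrast <- spectrum_contrast(spec_a, spec_b)
    plot_obj <- autoplot(contrast)
  }
  paths <- write_report(spectra, out_dir, "substitution_spectrum")
  if (!is.null(contrast)) {
    paths <- c(paths,
               write_report(as_tibble(contrast), out_dir,
                            "spectrum_contrast"))
  }
  plot_path <- file.path(out_dir,
                         paste0("substitution_spectrum.",
                                cfg$plot_format))
  ggplot2::ggsave(plot_path, plot_obj, width = 8, height = 4.5)
  paths <- c(paths, plot = plot_path)
  invisible(list(spectra = spectra, contrast = contrast, paths = paths))
}

#' Recessive-disease prioritization from VCF inputs
#'
#' Reads the case and control VCFs, the critical-interval BED and the
#' configured autosome list, runs [prioritize()] and writes the tiered
#' count report plus the surviving final-tier allele keys.
#'
#' @inheritParams run_truth_set
#' @return Invisibly, a list with the `report` and output `paths`.
#' @export
run_prioritize <- function(config) {
  cfg <- pipeline_config(config)
  out_dir <- ensure_out_dir(cfg)
  if (is.null(cfg$autosomes) || length(cfg$autosomes) == 0) {
    abort("Config field `autosomes` must list the autosomal contigs.")
  }
  cases <- read_vcf(cfg_path(cfg, "case_vcf"), cfg$case_samples)
  controls <- if (!is.null(cfg$control_vcf)) {
    read_vcf(cfg_path(cfg, "control_vcf"))
  } else {
    NULL
  }
  intervals <- read_bed(cfg_path(cfg, "interval_bed"))
  report <- prioritize(cases, controls, cases = cfg$case_samples,
                       intervals = intervals, autosomes = cfg$autosomes)
  wide <- tidyr::pivot_wider(report$counts, names_from = "sample",
                             values_from = "n")
  paths <- write_report(wide, out_dir, "prioritization_report")
  final <- report$keys[["private_protein_changing_in_interval"]]$shared
  paths <- c(paths,
             write_report(final, out_dir, "candidate_variants"))
  invisible(list(report = report, paths = paths))
}
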