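---
title: "Methods: benchmarking FFPE variant call sets and prioritizing recessive candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking FFPE variant call sets and prioritizing recessive candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpebench)
```

## The problem

Formalin-fixed paraffin-embedded (FFPE) tissue is often the only material
left for a retrospective genetic diagnosis. Fixation fragments DNA and
deaminates cytosine and 5-methylcytosine; the resulting dU:G and T:G
mismatches are read back as artifactual C>T (and, on the opposite strand,
G>A) substitutions. A call set from FFPE whole-genome sequencing is
therefore a mixture of genuine germline variation and a substantial
artifact load whose size depends on the caller's permissiveness.
`ffpebench` implements the downstream analysis for this setting: it
consumes VCFs (it does not align reads or call variants), builds a truth
set from the agreement of two callers on high-quality tissue, quantifies
how well FFPE-derived calls recover that truth, characterizes the
artifact spectrum, and runs the recessive-disease prioritization cascade
that asks whether the causal variant still falls out of the noise.

## The variant model

All set operations work on the **trimmed allele key** `(contig, pos, ref,
alt)`. On reading a VCF, multiallelic sites are decomposed into one record
per alternate allele; each sample's genotype is re-expressed relative to
the focal allele (other alternate alleles count as reference for that
record), and alleles are trimmed — shared trailing bases removed first,
then shared leading bases with the position advanced — until no shared
redundant base remains. This approximates the allele-level matching of
`bcftools isec` on normalized inputs without requiring a reference FASTA.

Two deliberate simplifications, and what they cost:

* **No reference-based left-alignment.** Trimming is purely intra-record.
  Two callers that place the same repeat-region indel at different
  anchors will produce different keys and the variant will land in both
  "unique" partitions. For SNVs and unambiguous indels the keys are
  identical to fully normalized ones.
* **Genotype classes, not allele depths.** Genotypes are classified as
  `hom_ref`, `het`, `hom_alt` or `missing`; phase and allele order are
  ignored. Any genotype containing a missing index (`./1`, `.`) is
  classed `missing` — the conservative reading for a recessive filter
  that names only `0/0`, `1/1` and `./.`. Haploid calls are likewise
  treated as missing rather than guessed at.

Contig names are opaque: no `chr` harmonization is attempted, and an
intersection across naming conventions is empty (the comparison functions
warn when two call sets share no contig names).

## Comparison metrics and their denominators

For one sample, the variant set on either side contains the keys at which
that sample's genotype is `het` or `hom_alt`; hom-ref and missing
genotypes are excluded from both totals. With TP/FP/FN defined by key
intersection:

* precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
  mean;
* false-negative rate = FN / truth total;
* **false-positive rate = FP / (TP + FP)** — the fraction of *query
  positives*, not of the truth set;
* **genotype concordance = concordant / TP** — concordant counts
  true-positive keys whose genotype classes match exactly, and the
  denominator is the *recovered* true positives, not the truth total.

The last two denominator conventions are not universal, so they are
pinned by arithmetic: the package's acceptance tests verify that exactly
these conventions reproduce the published percentages of the benchmark
tables shipped in `ffpe_study_counts()` (e.g. 648,346 / (3,921,247 +
648,346) = 14.19%). Ratios with zero denominators are reported as `NA`,
never as 0 — "undefined" and "perfectly clean" are different findings.
SNVs and indels are stratified before comparison; MNV records are
reported as their own stratum and excluded from both.

A handful of published cells are internally inconsistent with their own
printed counts (one dog's SNV TP count does not add up with its FN count
and truth total, and two concordance percentages disagree with their
printed numerator/denominator pair at the printed precision). The
acceptance tests assert every internally consistent cell and skip only
those, with the discrepancy documented in the test.

## Substitution spectra

Spectra use the twelve raw `ref>alt` classes rather than the six
strand-collapsed ones, because deamination is strand-asymmetric in the
read-level signal and the C>T and G>A excesses are the fingerprint being
looked for. Counts are scaled to calls per 10 Mb:

rate = count / (genome_size / 10^7), SE = sqrt(count) / (genome_size / 10^7)

The Poisson standard error treats each class count as a Poisson draw,
which is adequate for genome-wide counts and yields zero SE exactly when
the count is zero. `genome_size` has no default: the denominator belongs
to the genome the calls were made against, and inventing one would
silently change every rate. The cohort-mean spectrum (`sample = NULL`)
averages the per-sample class counts before scaling.

## Hard filters

The GATK-style thresholds (SNVs: QD < 2.0, QUAL < 30.0, SOR > 3.0,
FS > 60.0, MQ < 40.0, MQRankSum < −12.5, ReadPosRankSum < −8.0; indels:
QD < 2.0, QUAL < 30.0, FS > 200.0, ReadPosRankSum < −20.0, SOR > 10) are
applied with two policies worth stating:

* **Inequalities are strict exactly as written**; a record at the
  boundary (QD = 2.0) passes.
* **Absent annotations are skipped, never failed.** Rank-sum annotations
  only exist where a heterozygote informs them; failing on absence would
  mass-fail legitimate records. Skipped criteria are reported per record
  for audit.

MNV records are checked against the SNV thresholds (they are
substitution-like; the alternative of leaving them unfiltered would make
the MNV stratum systematically noisier). A bypass mode exists for callers
whose model already filters (DeepVariant-style output is conventionally
left unfiltered).

## Recessive prioritization

The cascade mirrors the standard private-homozygote screen: for each
affected case, keep keys where the case is `1/1`; drop any key where any
control is `het` or `hom_alt` (a single carrier control kills a fully
penetrant recessive candidate); keep impact MODERATE/HIGH
(protein-changing in the snpEff sense); keep configured autosomes; keep
the mapped critical interval (both interval ends inclusive). The "shared"
column intersects the per-case sets at every tier. Two modelling choices:

* A key **absent from the control call set is treated as missing in all
  controls**, not as hom-ref evidence — downstream of caller output one
  cannot distinguish "not variant" from "not genotyped". This is the
  permissive choice; with jointly genotyped controls it is exact.
* Other cases' genotypes do not constrain one case's private set; only
  controls do. Per-case columns are therefore independent screens and the
  shared column is their intersection.

Both tier monotonicity (counts never increase down the cascade) and
cohort monotonicity (adding a control never grows a private set) are
asserted as properties in the test suite.

## The synthetic-data generator

The generator produces call sets with the statistical structure the
analysis assumes, so every stage is testable without sequencing data. Its
defaults are the study conditions the package emulates; they are fixed
once and the tests measure against them.

* **Truth sets.** `n_snv + n_indel` records at unique positions on a toy
  genome of seven 10 Mb contigs (five autosomes, one X, one unplaced
  scaffold — big enough for stable ratios at 10^5 variants, small enough
  for seconds-scale tests). Substitution classes are drawn so transitions
  occur with probability t/(1+t) for target Ts/Tv t = 2.1; indels are
  deletions with probability d/(1+d) for target del/ins d = 1.04, with
  1–3 bp lengths. Defaults n_snv = 50,000 and n_indel = 19,000 keep the
  ~2.6:1 SNV:indel proportion of genome-wide call sets at desk scale.
* **Genotypes.** Per site, an alternate-allele frequency p ~ Beta(α, β)
  and Hardy–Weinberg genotypes per sample. The per-sample expected
  het/hom-alt ratio is then 2E[p(1−p)]/E[p²] = 2β/(α+1) — a closed form,
  so `calibrate_het_hom()` inverts it analytically rather than
  numerically (the tests confirm the calibration by simulation). Sites
  with no carrier are redrawn; because a site is always retained when
  the focal sample is non-reference, this ascertainment step does not
  bias per-sample het/hom. Default target 1.35 with α = 1.
* **Callers.** Records are missed with probability `fn_rate` (record
  level, all samples — a caller that misses a site misses it for the
  joint genotyping), surviving non-reference genotypes are class-swapped
  with probability `genotype_error_rate`, and Poisson(`fp_rate` × n)
  false records are appended at fresh positions. False SNVs get
  Ts/Tv ≈ 1 (random substitutions) and false records are heterozygous in
  every sample — both choices mirror the observed signatures of
  caller-unique call sets (low Ts/Tv, extreme het/hom). Defaults
  fn = 0.04, fp = 0.04, genotype error = 0.01, the scale of
  caller-vs-caller disagreement on fresh-frozen tissue.
* **FFPE artifacts.** Extra false SNVs are injected so that the
  cohort-mean C>T and G>A rates are multiplied by
  `deamination_multiplier` in expectation, with `extra_fp_rate`
  class-proportional background on all twelve classes. The enrichment is
  defined against the cohort-mean spectrum of the input call set, which
  makes the multiplier directly recoverable by `spectrum_contrast()`.
  Defaults 1.2 and 0.05, emulating the 15–20% transition inflation of
  permissively filtered FFPE call sets.
* **Cohorts.** Background SNV sites genotyped jointly across cases and
  controls under the same Hardy–Weinberg model, impact annotations from a
  background mixture (92% MODIFIER, 4% LOW, 3% MODERATE, 1% HIGH), 2%
  control genotypes set missing, and one planted causal variant inside
  the critical interval: `1/1` in every case, `0/0`/missing in every
  control, impact HIGH. The default critical interval places one segment
  on each of five autosomes (0.25 Mb each, ~1.8% of the toy genome),
  mirroring the few-segments-on-few-chromosomes structure of mapped
  intervals. Case and control call sets contain only the sites their own
  cohort carries, so the planted key is genuinely absent from the control
  VCF rather than present with reference genotypes.

All generators take a mandatory seed and are exactly reproducible —
identical call sets and byte-identical VCF output under the same seed.
Simplifications worth knowing when extrapolating to real data: reference
bases are uniform random (no trinucleotide context, so context-dependent
signatures cannot be studied), false positions never collide with truth
positions, errors are independent across sites (no mapping-difficulty
clustering), and no linkage disequilibrium exists between sites. Passing
tests on this generator demonstrate that the *analysis layer* measures
what it claims; they do not certify caller behaviour on real FFPE reads.

## Numerical and interface choices

* Undefined ratios are `NA` throughout; they propagate rather than
  masquerade as zeros.
* Published-table mirrors round percentages to two decimals in TSV
  reports; JSON reports carry full precision and identical numbers.
* VCF output is sorted by (contig, pos, ref, alt) for deterministic
  bytes; decomposition provenance survives round trips via an
  `OLD_MULTIALLELIC` INFO flag, and impact via a minimal snpEff-dialect
  `ANN` entry (impact in the third pipe-delimited subfield).
* Multiallelic-site counting uses distinct (contig, pos, ref) among
  flagged records; alleles of one site that trim to different anchors are
  counted separately (exact for multiallelic SNV sites).
* BED input is converted from 0-based half-open to the internal 1-based
  inclusive convention on read; intervals are merged when overlapping.
* Interval membership is a vectorized join; the test suite holds it (and
  the sample comparison) against brute-force double-loop oracles on
  small instances.

## Problem sizes used by the checks

The shipped verification suite runs the generator chain at 100,000
variants (80,000 SNVs + 20,000 indels) for parameter recovery — at that
size the 3-standard-error bands on Ts/Tv, recall, concordance and the
deamination multiplier are a few parts per thousand wide — and 100
seeded cohort simulations (3 cases, 200 controls, 2,000 background sites)
for planted-variant recovery, where the planted key is expected in the
final tier in every run and alone in it in at least 95%.
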