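#' Published FF/FFPE benchmarking counts
#'
#' Reported variant counts from a published comparison of germline variant
#' calling in matched fresh-frozen (FF) and FFPE whole genomes of three
#' dogs, analysed with two callers (GATK and DeepVariant). The counts are
#' the inputs from which that study's percentages derive; feeding them
#' through [performance_metrics()], [ts_tv_ratio()]-style arithmetic or
#' [del_ins_ratio()] arithmetic reproduces the published values, which is
#' used as a worked example and as an arithmetic cross-check of the metric
#' definitions.
#'
#' @return A list of two tibbles:
#' \describe{
#'   \item{benchmarks}{One row per evaluation panel x dog x variant class
#'     with `truth_total`, `query_total`, `tp`, `fp`, `fn` and
#'     `concordant` counts (`NA` where not reported). Panels:
#'     `ff_deepvariant_vs_gatk` (DeepVariant benchmarked against a GATK
#'     truth set on FF tissue), `ffpe_gatk` and `ffpe_deepvariant` (each
#'     caller's FFPE calls benchmarked against the FF truth set).}
#'   \item{ratios}{Transition/transversion and deletion/insertion counts
#'     per call-set partition (caller-unique and shared) and cohort.}
#' }
#' @export
#' @examples
#' counts <- ffpe_study_counts()
#' performance_metrics(counts$benchmarks)
ffpe_study_counts <- function() {
  benchmarks <- tribble(
    ~panel, ~dog, ~class, ~truth_total, ~query_total,
    ~tp, ~fp, ~fn, ~concordant,
    "ff_deepvariant_vs_gatk", 1L, "snv", 4150703, 4135339,
    3985449, 149890, 165254, NA,
    "ff_deepvariant_vs_gatk", 2L, "snv", 4158502, 4132691,
    3982023, 150668, 176479, NA,
    "ff_deepvariant_vs_gatk", 3L, "snv", 4158848, 4132647,
    3979168, 153479, 179680, NA,
    "ff_deepvariant_vs_gatk", 1L, "indel", 1909453, 1782062,
    1563156, 218906, 346297, NA,
    "ff_deepvariant_vs_gatk", 2L, "indel", 1915452, 1784162,
    1577855, 206307, 337597, NA,
    "ff_deepvariant_vs_gatk", 3L, "indel", 1903426, 1773434,
    1566681, 206753, 336745, NA,
    "ffpe_gatk", 1L, "snv", 4000130, NA,
    3921247, 648346, 78883, 3764256,
    "ffpe_gatk", 2L, "snv", 4002055, NA,
    3727751, 995747, 274304, 3487881,
    "ffpe_gatk", 3L, "snv", 3995612, NA,
    3811972, 807903, 142183, 3677866,
    "ffpe_gatk", 1L, "indel", 1560501, NA,
    1329857, 490105, 230644, 473905,
    "ffpe_gatk", 2L, "indel", 1562339, NA,
    1268732, 545605, 293607, 452145,
    "ffpe_gatk", 3L, "indel", 1554240, NA,
    1293729, 506477, 260511, 455234,
    "ffpe_deepvariant", 1L, "snv", 4000130, NA,
    3666386, 118767, 333744, 2961894,
    "ffpe_deepvariant", 2L, "snv", 4002055, NA,
    3350023, 108750, 652032, 2664263,
    "ffpe_deepvariant", 3L, "snv", 3995612, NA,
    3541117, 116733, 454495, 2847705,
    "ffpe_deepvariant", 1L, "indel", 1560501, NA,
    1259519, 208727, 300982, 551933,
    "ffpe_deepvariant", 2L, "indel", 1562339, NA,
    1147621, 182160, 414718, 495256,
    "ffpe_deepvariant", 3L, "indel", 1554240, NA,
    1211533, 198377, 342707, 521854
  )
  ratios <- tribble(
    ~cohort, ~partition, ~ts, ~tv, ~n_del, ~n_ins,
    "ff", "gatk_unique", NA, NA, 184152, 151227,
    "ff", "deepvariant_unique", NA, NA, 56262, 97685,
    "ff", "shared", NA, NA, 937206, 898956,
    "ffpe", "gatk_unique", 1089065, 856685, 475018, 454132,
    "ffpe", "deepvariant_unique", 47827, 55087, 113243, 149605,
    "ffpe", "shared", 3050681, 1444558, 801182, 705462
  )
  list(benchmarks = benchmarks, ratios = ratios)
}
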