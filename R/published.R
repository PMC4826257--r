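#' Published per-species summary statistics for drug-target comparisons
#'
#' Per-species summary tables from a published genome-wide comparison of
#' FDA-approved drug-target genes against Pfam-family-excluded
#' non-target genes over the 21-species panel: median, upper and lower
#' quartile of the feature in each group, plus the per-species Wilcoxon
#' rank-sum p-value. `feature = "dnds"` is the evolutionary rate table;
#' `feature = "conservation"` is the protein conservation-score table.
#'
#' These tables are pipeline *inputs*: feeding the paired per-species
#' medians to [signed_rank_test()] reproduces the published
#' cross-species significance levels. The underlying per-gene values
#' depend on specific external database releases and are not shipped.
#'
#' @param feature `"dnds"` or `"conservation"`.
#' @return A `data.frame` with columns `species`, `target_median`,
#'   `target_upper`, `target_lower`, `nontarget_median`,
#'   `nontarget_upper`, `nontarget_lower`, `rank_sum_p`.
#' @export
#' @examples
#' tab <- published_summary("dnds")
#' signed_rank_test(tab$target_median, tab$nontarget_median,
#'                  method = "normal_approx", tie_correction = FALSE)
published_summary <- function(feature = c("dnds", "conservation")) {
  feature <- match.arg(feature)
  file <- switch(feature,
                 dnds = "drugtarget_dnds_summary.tsv",
                 conservation = "drugtarget_conservation_summary.tsv")
  path <- system.file("extdata", file, package = "consurvey",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
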