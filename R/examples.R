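#' Published worked-example pair statistics
#'
#' Returns the per-pair statistics of the significant gene-metabolite pairs
#' reported in a two-breed pig feed-efficiency integration study: 21
#' breed-specific pairs (group 0 = Duroc, group 1 = Landrace) and 12
#' FE-specific pairs (group 0 = high-FE, group 1 = low-FE).  These small
#' tables serve as worked examples for the clustering, ordering and
#' significance-filter conventions; they are inputs, not outputs, of this
#' package.
#'
#' @param mode `"breed"` (21 pairs) or `"fe"` (12 pairs).
#' @return Data frame with columns `metabolite_id`, `gene_id`, `gene_name`,
#'   `cor_group0`, `cor_group1`, `diff_corr`, `p_interaction`, `fdr`.
#' @export
example_pair_stats <- function(mode = c("breed", "fe")) {
  mode <- match.arg(mode)
  fn <- if (mode == "breed") "breed_pair_stats.tsv" else "fe_pair_stats.tsv"
  path <- system.file("extdata", fn, package = "omicpairs", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
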