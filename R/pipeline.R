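# In-process orchestration of the full analysis.  The CLI subcommands are
# thin wrappers over these functions, so composing the stages on disk and
# calling run_pipeline() in memory give the same result tables.

#' Default analysis thresholds
#'
#' @return Named list: `count_threshold` (low-count filter, total count),
#'   `rsd_threshold` (metabolite relative-standard-deviation filter),
#'   `variance_fraction` (lowest-variance gene fraction removed),
#'   `fdr_max`, `min_abs_diff` (significance filters) and `raw_p_max`
#'   (optional raw interaction-p screen, off by default).
#' @export
default_thresholds <- function() {
  list(count_threshold = 1, rsd_threshold = 0.15, variance_fraction = 0.05,
       fdr_max = 0.1, min_abs_diff = 0.1, raw_p_max = NULL)
}

#' Phenotype coding for an analysis mode
#'
#' Breed mode codes Duroc as group 0 and Landrace as group 1; FE mode codes
#' the high-FE group as 0 and low-FE as 1.  This makes the signed
#' correlation difference read Landrace minus Duroc / low minus high.
#'
#' @param mode `"breed"` or `"fe"`.
#' @return A [phenotype_coding()].
#' @export
default_coding <- function(mode = c("breed", "fe")) {
  mode <- match.arg(mode)
  if (mode == "breed")
    phenotype_coding("breed", level0 = "duroc", level1 = "landrace",
                     mode = "breed")
  else
    phenotype_coding("fe_group", level0 = "high", level1 = "low",
                     mode = "fe")
}

#' Preprocess both omics layers
#'
#' Genes: low-count filter, size-factor normalization, negative-value
#' screen, lowest-variance filter.  Metabolites: RSD filter on the raw
#' scale, then natural-log transform.
#'
#' @param counts Gene counts [omics_matrix()] (`layer_tag = "counts"`).
#' @param abundances Metabolite abundances (`layer_tag = "raw_abundance"`).
#' @param thresholds See [default_thresholds()].
#' @return List with `genes`, `metabolites` (omics matrices) and `funnel`
#'   (list of [filter_report()]s, in order of application).
#' @export
preprocess_all <- function(counts, abundances,
                           thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  funnel <- list()
  lc <- filter_low_count_genes(counts, threshold = th$count_threshold)
  funnel <- c(funnel, list(lc$report))
  gn <- normalize_counts(lc$matrix)
  nn <- nonneg_filter(gn)
  funnel <- c(funnel, list(nn$report))
  vf <- variance_filter(nn$matrix, fraction = th$variance_fraction)
  funnel <- c(funnel, list(vf$report))
  rf <- rsd_filter(abundances, threshold = th$rsd_threshold)
  funnel <- c(funnel, list(rf$report))
  ml <- log_normalize_metabolites(rf$matrix)
  list(genes = vf$matrix, metabolites = ml, funnel = funnel)
}

#' Adjust both layers for the mode-appropriate nuisance covariates
#'
#' @param genes Normalized gene matrix.
#' @param metabolites Log-abundance matrix.
#' @param meta Sample metadata.
#' @param mode `"breed"` or `"fe"`; the phenotype under test is never part
#'   of its own adjustment.
#' @return List with adjusted `genes` and `metabolites`.
#' @export
adjust_all <- function(genes, metabolites, meta, mode = c("breed", "fe")) {
  mode <- match.arg(mode)
  ord <- match(colnames(genes), meta$sample_id)
  if (anyNA(ord))
    stop("metadata lacks sample(s): ",
         paste(setdiff(colnames(genes), meta$sample_id), collapse = ", "),
         call. = FALSE)
  meta <- meta[ord, , drop = FALSE]
  dg <- build_design(meta, default_design(mode, "genes"))
  dm <- build_design(meta, default_design(mode, "metabolites"))
  list(genes = adjust_covariates(genes, dg),
       metabolites = adjust_covariates(metabolites, dm))
}

#' Run the full integration pipeline in memory
#'
#' Preprocess, adjust, fit all pairs, filter, cluster, and (if a pathway
#' library is given) run metabolite over-representation per cluster with
#' the preprocessed metabolite set as the universe.
#'
#' @param counts,abundances,meta,library Inputs (library may be `NULL`).
#' @param mode `"breed"` or `"fe"`.
#' @param thresholds See [default_thresholds()].
#' @param block_size Gene block size for the pair engine.
#' @return List: `preprocessed`, `adjusted`, `results` (all pairs),
#'   `significant` (clustered), `cluster_summary`, `ordered` (heatmap
#'   order), `ora` (or `NULL`), `model_count`.
#' @export
run_pipeline <- function(counts, abundances, meta, library = NULL,
                         mode = c("breed", "fe"),
                         thresholds = default_thresholds(),
                         block_size = 1024L) {
  mode <- match.arg(mode)
  th <- utils::modifyList(default_thresholds(), thresholds)
  pre <- preprocess_all(counts, abundances, th)
  adj <- adjust_all(pre$genes, pre$metabolites, meta, mode)
  meta_o <- meta[match(colnames(pre$genes), meta$sample_id), , drop = FALSE]
  coding <- default_coding(mode)
  res <- run_all_pairs(adj$genes, adj$metabolites, meta_o, coding,
                       block_size = block_size)
  sig <- filter_significant(res, fdr_max = th$fdr_max,
                            min_abs_diff = th$min_abs_diff,
                            raw_p_max = th$raw_p_max)
  sig <- assign_clusters(sig, reference = "group0")
  summ <- summarize_clusters(sig)
  ordered <- order_for_heatmap(sig)
  ora <- NULL
  if (!is.null(library) && nrow(sig)) {
    universe <- rownames(pre$metabolites)
    ora_rows <- lapply(unique(sig$cluster), function(cl) {
      hits <- unique(sig$metabolite_id[sig$cluster == cl])
      o <- hypergeom_ora(hits, universe, library)
      o$cluster <- cl
      o
    })
    ora <- do.call(rbind, c(ora_rows, list(make.row.names = FALSE)))
  }
  list(preprocessed = pre, adjusted = adj, results = res, significant = sig,
       cluster_summary = summ, ordered = ordered, ora = ora,
       model_count = attr(res, "model_count"))
}
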