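# Direction clusters of significant pairs.  A pair is "reference
# correlated" if its correlation in the reference phenotype group is
# positive and "reference anticorrelated" if negative; with divergent pairs
# this splits the significant set into the two blocks seen in
# direction-sorted correlation heatmaps.

CLUSTER_LEVELS <- c("ref_correlated", "ref_anticorrelated")

#' Assign direction clusters to significant pairs
#'
#' @param significant Data frame of pair results carrying `cor_group0` and
#'   `cor_group1`.
#' @param reference `"group0"` or `"group1"`: which group's correlation
#'   sign keys the cluster (group 0 is Duroc / high-FE under the package's
#'   coding conventions).
#' @return `significant` with a `cluster` column added.  An exactly-zero
#'   reference correlation goes to `ref_anticorrelated` with a warning
#'   (arbitrary but deterministic; does not occur on continuous data).
#' @export
assign_clusters <- function(significant, reference = c("group0", "group1")) {
  reference <- match.arg(reference)
  col <- if (reference == "group0") "cor_group0" else "cor_group1"
  stopifnot(col %in% names(significant))
  refcor <- significant[[col]]
  if (any(refcor == 0) && nrow(significant))
    warning("pair(s) with exactly zero reference correlation assigned to ",
            "ref_anticorrelated", call. = FALSE)
  significant$cluster <- ifelse(refcor > 0, "ref_correlated",
                                "ref_anticorrelated")
  significant
}

#' Summarize one direction cluster
#'
#' Counts pairs and deduplicates the genes and metabolites involved (one
#' feature may participate in several pairs).
#'
#' @param pairs Data frame of pairs from a single cluster.
#' @return List with `cluster`, `n_pairs`, sorted `unique_metabolites` and
#'   `unique_genes`; empty input yields an empty summary.
#' @export
summarize_cluster <- function(pairs) {
  list(cluster = if (nrow(pairs)) unique(pairs$cluster)[1L] else NA_character_,
       n_pairs = nrow(pairs),
       unique_metabolites = sort(unique(pairs$metabolite_id)),
       unique_genes = sort(unique(pairs$gene_id)))
}

#' Summarize all clusters of a significant-pair table
#'
#' @param significant Output of [assign_clusters()].
#' @return Data frame with one row per non-empty cluster: `cluster`,
#'   `n_pairs`, `n_unique_metabolites`, `n_unique_genes`.
#' @export
summarize_clusters <- function(significant) {
  stopifnot("cluster" %in% names(significant))
  present <- intersect(CLUSTER_LEVELS, unique(significant$cluster))
  rows <- lapply(present, function(cl) {
    s <- summarize_cluster(significant[significant$cluster == cl, ,
                                       drop = FALSE])
    data.frame(cluster = cl, n_pairs = s$n_pairs,
               n_unique_metabolites = length(s$unique_metabolites),
               n_unique_genes = length(s$unique_genes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cluster = character(), n_pairs = integer(),
                      n_unique_metabolites = integer(),
                      n_unique_genes = integer())
  out
}

#' Order pairs for a direction-sorted heatmap
#'
#' Sorts by cluster (`ref_correlated` first), then by descending absolute
#' correlation difference, breaking ties by metabolite then gene ID; this
#' is the display order of the correlation heatmaps.
#'
#' @param pairs Data frame with `cluster` and `diff_corr` columns.
#' @return The reordered data frame.
#' @export
order_for_heatmap <- function(pairs) {
  stopifnot(all(c("cluster", "diff_corr") %in% names(pairs)))
  if (!nrow(pairs)) return(pairs)
  ord <- order(match(pairs$cluster, CLUSTER_LEVELS),
               -abs(pairs$diff_corr), pairs$metabolite_id, pairs$gene_id)
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-group correlation matrix of ordered pairs (for display)
#'
#' @param pairs Ordered pairs (see [order_for_heatmap()]).
#' @return Numeric matrix (pairs x 2 groups) of Spearman correlations with
#'   `metabolite_id:gene_id` row labels.
#' @export
pair_correlation_matrix <- function(pairs) {
  m <- cbind(group0 = pairs$cor_group0, group1 = pairs$cor_group1)
  rownames(m) <- paste(pairs$metabolite_id, pairs$gene_id, sep = ":")
  m
}

#' Optional heatmap of the significant pairs
#'
#' Draws (or writes to PNG) a direction-sorted two-column heatmap of the
#' per-group correlations.  Requires the `pheatmap` package.
#'
#' @param pairs Pair results with clusters assigned.
#' @param path Optional PNG output path.
#' @return The pheatmap object, invisibly; `NULL` if pheatmap is missing.
#' @export
plot_pair_heatmap <- function(pairs, path = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    warning("pheatmap not installed; skipping heatmap", call. = FALSE)
    return(invisible(NULL))
  }
  m <- pair_correlation_matrix(order_for_heatmap(pairs))
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 120 + 20 * nrow(m))
    on.exit(grDevices::dev.off())
  }
  ph <- pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE)
  invisible(ph)
}
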