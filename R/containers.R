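#' @keywords internal
"_PACKAGE"

# Layer tags an omics matrix can carry.  `counts` is raw non-negative
# integers, everything else is continuous.
LAYER_TAGS <- c("counts", "normalized", "adjusted", "raw_abundance",
                "log_abundance")

#' Construct an omics matrix
#'
#' A features-by-samples numeric matrix with unique feature and sample
#' identifiers and a layer tag recording what the values are (raw counts,
#' normalized expression, raw or log metabolite abundance, or
#' covariate-adjusted values).
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature identifiers, column names are sample identifiers.
#' @param layer_tag One of `"counts"`, `"normalized"`, `"adjusted"`,
#'   `"raw_abundance"`, `"log_abundance"`.
#' @return A matrix of class `omics_matrix` with a `layer_tag` attribute.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' om <- omics_matrix(m, "counts")
#' layer_tag(om)
#' @export
omics_matrix <- function(values, layer_tag) {
  layer_tag <- match.arg(layer_tag, LAYER_TAGS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("omics matrix must have at least one feature and one sample",
         call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics matrix needs feature (row) and sample (column) names",
         call. = FALSE)
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (anyNA(values))
    stop("missing values are not allowed in an omics matrix", call. = FALSE)
  if (layer_tag == "counts" && any(values < 0))
    stop("a counts layer cannot contain negative values", call. = FALSE)
  structure(values, layer_tag = layer_tag,
            class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
layer_tag <- function(x) attr(x, "layer_tag")

#' @rdname omics_matrix
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples, layer = %s\n",
              nrow(x), ncol(x), layer_tag(x)))
  invisible(x)
}

# Re-tag a matrix, keeping the class.  Internal: used when a transform
# changes the meaning of the values.
retag <- function(x, layer_tag) {
  out <- unclass(x)
  omics_matrix(out, layer_tag)
}

#' Validate a sample metadata table
#'
#' Checks that a data frame of per-sample phenotype labels and covariates
#' has one row per sample and that the categorical columns have the declared
#' level sets (breed and metabolomics batch: 2 levels; feed-efficiency
#' group: high/low; pen: up to 8 levels by default).
#'
#' @param meta Data frame with at least a `sample_id` column.
#' @param required Character vector of columns that must be present.
#' @return `meta`, invisibly, with `sample_id` as character.
#' @export
validate_sample_table <- function(meta,
                                  required = c("sample_id")) {
  if (!is.data.frame(meta)) stop("`meta` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup))
    stop("duplicate sample IDs in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if ("fe_group" %in% names(meta)) {
    bad <- setdiff(unique(as.character(meta$fe_group)), c("high", "low"))
    if (length(bad))
      stop("fe_group must be 'high' or 'low', found: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(meta)
}

#' Construct a pathway library
#'
#' Named feature sets (for example KEGG-style metabolite sets), optionally
#' with a per-set graph of feature-feature edges used for topology scoring.
#'
#' @param sets Named list; each element a character vector of feature IDs.
#' @param graphs Optional named list of edge data frames (columns `from`,
#'   `to`), one per set.
#' @return Object of class `pathway_library`.
#' @export
pathway_library <- function(sets, graphs = NULL) {
  if (length(sets) && is.null(names(sets)))
    stop("pathway sets must be named", call. = FALSE)
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L)
      stop("pathway set '", nm, "' is empty", call. = FALSE)
    if (anyDuplicated(sets[[nm]]))
      stop("pathway set '", nm, "' has duplicate members", call. = FALSE)
  }
  structure(list(sets = sets, graphs = graphs), class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("<pathway_library> %d sets (sizes %s)\n", length(x$sets),
              if (length(x$sets)) paste(range(lengths(x$sets)),
                                        collapse = "-") else "-"))
  invisible(x)
}

#' Construct a filter report
#'
#' Records, for one filtering stage, how many features went in, how many
#' survived, and which were removed, so the preprocessing funnel can be
#' reconstructed from logs.
#'
#' @param stage Stage name.
#' @param features_in Number of features before the filter.
#' @param removed_ids Character vector of removed feature IDs.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(stage, features_in, removed_ids) {
  out <- list(stage = stage,
              features_in = as.integer(features_in),
              features_out = as.integer(features_in - length(removed_ids)),
              removed_ids = as.character(removed_ids))
  stopifnot(out$features_out >= 0L)
  structure(out, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] features: %d -> %d (%d removed)\n", x$stage,
              x$features_in, x$features_out, length(x$removed_ids)))
  invisible(x)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}
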