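# Feature filtering and normalization for both omics layers.  Each filter
# returns the filtered matrix together with a filter_report so the
# preprocessing funnel (features in -> features out per stage) can be
# reconstructed from logs.

#' Remove genes with (essentially) no counts
#'
#' Drops genes whose total count across samples is below `threshold`.  With
#' the default threshold of 1 and integer counts this removes exactly the
#' all-zero genes.  Set `per_sample_mean = TRUE` to apply the threshold to
#' the per-sample mean count instead of the total.
#'
#' @param counts An [omics_matrix()] with `layer_tag == "counts"`.
#' @param threshold Minimum total (or mean) count for a gene to be kept.
#' @param per_sample_mean Apply `threshold` to the mean count per sample.
#' @return `list(matrix = <filtered omics_matrix>, report = <filter_report>)`.
#' @export
filter_low_count_genes <- function(counts, threshold = 1,
                                   per_sample_mean = FALSE) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (layer_tag(counts) != "counts")
    stop("filter_low_count_genes expects a counts layer, got '",
         layer_tag(counts), "'", call. = FALSE)
  stat <- rowSums(counts)
  if (per_sample_mean) stat <- stat / ncol(counts)
  keep <- stat >= threshold
  removed <- rownames(counts)[!keep]
  rep <- filter_report("low_count", nrow(counts), removed)
  log_stage("low_count", "features: %d -> %d", rep$features_in,
            rep$features_out)
  if (!any(keep))
    stop("all genes removed by the low-count filter", call. = FALSE)
  list(matrix = retag(counts[keep, , drop = FALSE], "counts"), report = rep)
}

#' Size-factor normalize a count matrix
#'
#' Variance-flattening stand-in for a variance stabilizing transformation:
#' per-sample size factors are computed by the median-of-ratios method
#' against the geometric-mean reference (genes containing any zero are
#' excluded from the reference), and each count is mapped to
#' `log2(count / size_factor + 1)`.
#'
#' @param counts An [omics_matrix()] with `layer_tag == "counts"`.
#' @return An [omics_matrix()] with `layer_tag == "normalized"` and a
#'   `size_factors` attribute.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "omics_matrix"))
  if (layer_tag(counts) != "counts")
    stop("normalize_counts expects a counts layer", call. = FALSE)
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "), call. = FALSE)
  ref_ok <- rowSums(counts == 0) == 0L
  if (!any(ref_ok))
    stop("no zero-free genes available for the geometric-mean reference",
         call. = FALSE)
  logref <- rowMeans(log(counts[ref_ok, , drop = FALSE]))
  sf <- apply(counts[ref_ok, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - logref)))
  out <- log2(sweep(unclass(counts), 2L, sf, "/") + 1)
  out <- omics_matrix(out, "normalized")
  attr(out, "size_factors") <- sf
  out
}

#' Filter metabolites by relative standard deviation
#'
#' Keeps metabolites whose relative standard deviation (sample standard
#' deviation, denominator n-1, divided by the mean) exceeds `threshold`,
#' computed on the raw abundance scale.  Near-constant metabolites carry no
#' usable signal for correlation analysis and are dropped.
#'
#' @param abundances An [omics_matrix()] with `layer_tag == "raw_abundance"`.
#' @param threshold RSD cutoff; features with RSD > threshold are kept.
#' @return `list(matrix = ..., report = ...)` as in
#'   [filter_low_count_genes()].
#' @export
rsd_filter <- function(abundances, threshold = 0.15) {
  stopifnot(inherits(abundances, "omics_matrix"))
  if (layer_tag(abundances) != "raw_abundance")
    stop("rsd_filter expects a raw_abundance layer", call. = FALSE)
  mu <- rowMeans(abundances)
  if (any(mu == 0))
    stop("zero-mean feature(s), RSD undefined: ",
         paste(rownames(abundances)[mu == 0], collapse = ", "),
         call. = FALSE)
  sdv <- apply(abundances, 1L, stats::sd)
  keep <- sdv / mu > threshold
  removed <- rownames(abundances)[!keep]
  rep <- filter_report("rsd", nrow(abundances), removed)
  log_stage("rsd", "threshold %.3g, features: %d -> %d", threshold,
            rep$features_in, rep$features_out)
  list(matrix = retag(abundances[keep, , drop = FALSE], "raw_abundance"),
       report = rep)
}

#' Natural-log transform metabolite abundances
#'
#' @param abundances An [omics_matrix()] with strictly positive values.
#' @return An [omics_matrix()] with `layer_tag == "log_abundance"`.
#' @export
log_normalize_metabolites <- function(abundances) {
  stopifnot(inherits(abundances, "omics_matrix"))
  bad <- which(unclass(abundances) <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonpositive abundance at feature '%s', sample '%s'",
                 rownames(abundances)[bad[1L, 1L]],
                 colnames(abundances)[bad[1L, 2L]]), call. = FALSE)
  retag(log(unclass(abundances)), "log_abundance")
}

#' Remove the lowest-variance fraction of features
#'
#' Removes the `ceiling(fraction * n)` features with the smallest sample
#' variance; ties are broken by feature-ID lexical order (stable and
#' documented), so the retained count is always `n - ceiling(fraction * n)`.
#'
#' @param x An [omics_matrix()].
#' @param fraction Fraction of features to remove, in `[0, 1)`.
#' @return `list(matrix = ..., report = ...)`.
#' @export
variance_filter <- function(x, fraction = 0.05) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  n <- nrow(x)
  n_remove <- ceiling(fraction * n)
  v <- apply(x, 1L, stats::var)
  ord <- order(v, rownames(x), method = "radix")
  removed <- rownames(x)[ord[seq_len(n_remove)]]
  keep <- !(rownames(x) %in% removed)
  rep <- filter_report("variance", n, removed)
  log_stage("variance", "fraction %.3g, features: %d -> %d", fraction,
            rep$features_in, rep$features_out)
  list(matrix = retag(x[keep, , drop = FALSE], layer_tag(x)), report = rep)
}

#' Remove features containing negative values
#'
#' After normalization/adjustment some features can go negative on the
#' transformed scale; this screen drops any feature with at least one
#' negative entry.
#'
#' @param x An [omics_matrix()] with a `normalized` or `adjusted` layer.
#' @return `list(matrix = ..., report = ...)`.
#' @export
nonneg_filter <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!layer_tag(x) %in% c("normalized", "adjusted"))
    stop("nonneg_filter expects a normalized or adjusted layer", call. = FALSE)
  keep <- rowSums(unclass(x) < 0) == 0L
  removed <- rownames(x)[!keep]
  rep <- filter_report("nonneg", nrow(x), removed)
  log_stage("nonneg", "features: %d -> %d", rep$features_in, rep$features_out)
  list(matrix = retag(x[keep, , drop = FALSE], layer_tag(x)), report = rep)
}

#' Classify samples into phenotype tails by standard deviation
#'
#' Labels each value `"low"` if it is at or below `mean - k * sd`, `"high"`
#' if at or above `mean + k * sd`, and `"excluded"` otherwise, computed
#' independently within each stratum (typically breed).  Applied to feed
#' conversion ratio (FCR) this yields the divergent groups: low FCR means
#' high feed efficiency, so downstream code maps FCR label `"low"` to FE
#' group `"high"` and vice versa (see the returned `fe_map` attribute).
#'
#' @param values Numeric vector (for example per-animal FCR).
#' @param strata Optional factor-like vector of the same length; the
#'   classification is done within each stratum independently.
#' @param k Number of standard deviations from the stratum mean.
#' @return Character vector of labels in `{"low", "high", "excluded"}` with
#'   an `fe_map` attribute giving the FCR-label to FE-group mapping.
#' @export
classify_by_sd <- function(values, strata = NULL, k = 1) {
  if (is.null(strata)) strata <- rep("all", length(values))
  stopifnot(length(strata) == length(values), k >= 0)
  out <- character(length(values))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(idx) < 3L)
      stop("stratum '", s, "' has fewer than 3 values", call. = FALSE)
    v <- values[idx]
    m <- mean(v)
    sdv <- stats::sd(v)
    if (sdv == 0) {
      warning("stratum '", s, "' has zero variance; all samples excluded",
              call. = FALSE)
      out[idx] <- "excluded"
      next
    }
    lab <- rep("excluded", length(idx))
    lab[v <= m - k * sdv] <- "low"
    lab[v >= m + k * sdv] <- "high"
    out[idx] <- lab
  }
  # low FCR = efficient animal = high-FE group
  attr(out, "fe_map") <- c(low = "high", high = "low")
  out
}
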