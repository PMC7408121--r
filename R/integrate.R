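# The core engine: for every gene-metabolite pair, ordinary least squares
# of the metabolite on [1, g, p, g*p] with p a 0/1 phenotype.  The
# interaction coefficient beta4 is the slope difference between the groups;
# its two-tailed t probability (df = n - 4), BH-FDR across the full family
# of fitted pairs, per-group Spearman correlations and their signed
# difference drive the significance filters.

#' Phenotype coding for the integration model
#'
#' Fixes which metadata column carries the binary phenotype and which level
#' is coded 0 and 1.  By convention group 0 is Duroc (breed mode) or the
#' high-FE group (FE mode), so the signed correlation difference
#' `cor_group1 - cor_group0` reads Landrace minus Duroc, or low-FE minus
#' high-FE.
#'
#' @param column Metadata column name holding the phenotype.
#' @param level0,level1 Labels coded 0 and 1 respectively.
#' @param mode `"breed"` or `"fe"` (bookkeeping only).
#' @return Object of class `phenotype_coding`.
#' @export
phenotype_coding <- function(column, level0, level1,
                             mode = c("breed", "fe")) {
  mode <- match.arg(mode)
  if (identical(level0, level1))
    stop("level0 and level1 must differ", call. = FALSE)
  structure(list(column = column, level0 = level0, level1 = level1,
                 mode = mode), class = "phenotype_coding")
}

#' Encode a metadata column as a 0/1 phenotype vector
#' @param meta Sample metadata data frame.
#' @param coding A [phenotype_coding()].
#' @return Integer vector of 0/1, named by sample ID.
#' @export
encode_phenotype <- function(meta, coding) {
  stopifnot(inherits(coding, "phenotype_coding"))
  if (!coding$column %in% names(meta))
    stop("metadata lacks phenotype column '", coding$column, "'",
         call. = FALSE)
  v <- as.character(meta[[coding$column]])
  bad <- setdiff(unique(v), c(coding$level0, coding$level1))
  if (length(bad))
    stop("unexpected phenotype level(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(c(coding$level0, coding$level1) %in% v))
    stop("both phenotype levels must be present among the samples",
         call. = FALSE)
  stats::setNames(as.integer(v == coding$level1), meta$sample_id)
}

# Cap a p-value away from exact zero (perfect fits underflow the t tail).
cap_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

#' Fit the interaction model for a single gene-metabolite pair
#'
#' OLS of `m` on `[1, g, p, g*p]`.  `beta4` is the group difference in the
#' gene-metabolite slope; `p_interaction` is its two-tailed t probability
#' with `n - 4` degrees of freedom.  A pair whose design is singular
#' (for example a constant gene) is reported with `p_interaction = 1` and
#' `singular = TRUE` rather than failing.
#'
#' @param g,m Numeric vectors of gene and metabolite values (same samples,
#'   same order).
#' @param p Integer 0/1 phenotype vector; both levels need >= 3 samples.
#' @return One-row data frame with coefficients, `se_beta4`,
#'   `p_interaction`, per-group Spearman correlations, the signed
#'   correlation difference and flags.
#' @export
fit_pair <- function(g, m, p) {
  n <- length(g)
  stopifnot(length(m) == n, length(p) == n)
  if (n < 6L) stop("need at least 6 samples", call. = FALSE)
  if (anyNA(g) || anyNA(m) || anyNA(p))
    stop("missing values are not allowed", call. = FALSE)
  if (!all(p %in% c(0L, 1L)))
    stop("phenotype must be coded 0/1", call. = FALSE)
  if (min(sum(p == 0L), sum(p == 1L)) < 3L)
    stop("each phenotype group needs >= 3 samples", call. = FALSE)

  X <- cbind(1, g, p, g * p)
  qrX <- qr(X)
  singular <- qrX$rank < 4L
  if (singular) {
    beta <- rep(NA_real_, 4L)
    se4 <- NA_real_
    pval <- 1
  } else {
    beta <- drop(qr.coef(qrX, m))
    res <- drop(qr.resid(qrX, m))
    df <- n - 4L
    sigma2 <- sum(res^2) / df
    XtX_inv <- chol2inv(qr.R(qrX))
    se4 <- sqrt(sigma2 * XtX_inv[4L, 4L])
    tval <- if (se4 > 0) beta[4L] / se4 else if (beta[4L] == 0) 0 else Inf
    pval <- cap_p(2 * stats::pt(abs(tval), df = df, lower.tail = FALSE))
  }
  sp <- spearman_by_group(g, m, p)
  data.frame(beta1 = beta[1L], beta2 = beta[2L], beta3 = beta[3L],
             beta4 = beta[4L], se_beta4 = se4, p_interaction = pval,
             cor_group0 = sp[1L], cor_group1 = sp[2L],
             diff_corr = correlation_difference(sp[1L], sp[2L]),
             abs_diff_corr = abs(correlation_difference(sp[1L], sp[2L])),
             singular = singular)
}

#' Per-group Spearman correlation
#'
#' Rank correlation of `g` and `m` within each phenotype group separately;
#' ties get average ranks.  A constant vector within a group yields a
#' correlation of 0 (flagged via attribute `degenerate`).
#'
#' @inheritParams fit_pair
#' @return Numeric vector `c(cor_group0, cor_group1)`.
#' @export
spearman_by_group <- function(g, m, p) {
  out <- numeric(2L)
  degen <- logical(2L)
  for (s in 0:1) {
    idx <- p == s
    if (sum(idx) < 3L) stop("each group needs >= 3 samples", call. = FALSE)
    gs <- g[idx]; ms <- m[idx]
    if (stats::sd(gs) == 0 || stats::sd(ms) == 0) {
      out[s + 1L] <- 0
      degen[s + 1L] <- TRUE
    } else {
      out[s + 1L] <- stats::cor(rank(gs), rank(ms))
    }
  }
  attr(out, "degenerate") <- degen
  out
}

#' Signed correlation difference
#'
#' `cor_group1 - cor_group0`.  With the package's coding conventions this
#' is Landrace minus Duroc (breed mode) or low-FE minus high-FE (FE mode).
#' Despite often being tabulated under an "absolute difference" heading,
#' the quantity is signed; use `abs()` for the effect-size screen.
#'
#' @param cor_group0,cor_group1 Per-group correlations.
#' @return `cor_group1 - cor_group0`.
#' @export
correlation_difference <- function(cor_group0, cor_group1) {
  unname(cor_group1 - cor_group0)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.  Written out explicitly (rather than delegating) so the
#' procedure is auditable against the hand-evaluated step-up.
#'
#' @param pvalues Numeric vector with all values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvalues)
  if (m == 0L) return(numeric())
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
  adj
}

#' Fit the interaction model for every gene-metabolite pair
#'
#' Runs `n_genes * n_metabolites` models with a blocked closed-form OLS
#' (per-group cross-products), equivalent to calling [fit_pair()] on every
#' pair but several orders of magnitude faster.  FDR is computed across the
#' full family of fitted pairs.
#'
#' @param genes,metabolites [omics_matrix()] objects (typically adjusted)
#'   over the identical ordered sample set.
#' @param meta Sample metadata containing the phenotype column.
#' @param coding A [phenotype_coding()].
#' @param block_size Number of genes fitted per block (memory bound).
#' @param dry_run If `TRUE`, validate inputs and return only the model
#'   count without fitting.
#' @return Data frame of class `pair_results` (one row per pair, columns
#'   `metabolite_id, gene_id, beta1..beta4, se_beta4, p_interaction, fdr,
#'   cor_group0, cor_group1, diff_corr, abs_diff_corr, singular`) with
#'   attribute `model_count`.  For `dry_run = TRUE`, the model count.
#' @export
run_all_pairs <- function(genes, metabolites, meta, coding,
                          block_size = 1024L, dry_run = FALSE) {
  stopifnot(inherits(genes, "omics_matrix"),
            inherits(metabolites, "omics_matrix"))
  if (!identical(colnames(genes), colnames(metabolites))) {
    off <- union(setdiff(colnames(genes), colnames(metabolites)),
                 setdiff(colnames(metabolites), colnames(genes)))
    stop("sample sets differ or are ordered differently",
         if (length(off)) paste0("; offending IDs: ",
                                 paste(off, collapse = ", ")) else "",
         call. = FALSE)
  }
  if (!identical(colnames(genes), as.character(meta$sample_id)))
    stop("metadata rows do not align with matrix samples", call. = FALSE)
  model_count <- nrow(genes) * nrow(metabolites)
  log_stage("integrate", "fitting %d x %d = %s models",
            nrow(genes), nrow(metabolites),
            format(model_count, big.mark = ","))
  if (dry_run) return(model_count)

  p <- encode_phenotype(meta, coding)
  n <- length(p)
  if (n < 6L) stop("need at least 6 samples", call. = FALSE)
  if (min(sum(p == 0L), sum(p == 1L)) < 3L)
    stop("each phenotype group needs >= 3 samples", call. = FALSE)
  df <- n - 4L

  M <- unclass(metabolites)
  G <- unclass(genes)
  idx0 <- which(p == 0L); idx1 <- which(p == 1L)
  n0 <- length(idx0); n1 <- length(idx1)

  group_stats <- function(Gb, Ms, idx) {
    Gc <- Gb[, idx, drop = FALSE]
    Mc <- Ms[, idx, drop = FALSE]
    gbar <- rowMeans(Gc); mbar <- rowMeans(Mc)
    Gcc <- Gc - gbar
    Mcc <- Mc - mbar
    list(gbar = gbar, mbar = mbar,
         sxx = rowSums(Gcc^2), syy = rowSums(Mcc^2),
         sxy = Gcc %*% t(Mcc))
  }

  # Spearman: rank within group once, on the full matrices.
  rank_rows <- function(A, idx) t(apply(A[, idx, drop = FALSE], 1L, rank))
  Gr0 <- rank_rows(G, idx0); Gr1 <- rank_rows(G, idx1)
  Mr0 <- rank_rows(M, idx0); Mr1 <- rank_rows(M, idx1)
  safe_cor <- function(X, Y) {
    # Pearson on ranks; constant rows (zero sd) -> 0 by convention
    suppressWarnings(cc <- stats::cor(t(X), t(Y)))
    cc[is.na(cc)] <- 0
    cc
  }

  blocks <- split(seq_len(nrow(G)),
                  ceiling(seq_len(nrow(G)) / max(1L, block_size)))
  res_list <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- blocks[[bi]]
    Gb <- G[rows, , drop = FALSE]
    s0 <- group_stats(Gb, M, idx0)
    s1 <- group_stats(Gb, M, idx1)

    ok0 <- s0$sxx > 0; ok1 <- s1$sxx > 0
    sxx0 <- ifelse(ok0, s0$sxx, NA_real_)
    sxx1 <- ifelse(ok1, s1$sxx, NA_real_)

    slope0 <- s0$sxy / sxx0               # genes x metabolites
    slope1 <- s1$sxy / sxx1
    beta2 <- slope0
    beta4 <- slope1 - slope0
    int0 <- sweep(-slope0 * s0$gbar, 2L, s0$mbar, "+")
    int1 <- sweep(-slope1 * s1$gbar, 2L, s1$mbar, "+")
    beta1 <- int0
    beta3 <- int1 - int0

    rss <- sweep(-s0$sxy^2 / sxx0, 2L, s0$syy, "+") +
           sweep(-s1$sxy^2 / sxx1, 2L, s1$syy, "+")
    rss[rss < 0] <- 0                      # numerical guard
    sigma2 <- rss / df
    se4 <- sqrt(sigma2 * (1 / sxx0 + 1 / sxx1))
    tval <- beta4 / se4
    zero_se <- which(se4 == 0)            # perfect fit: t is 0/0 or x/0
    tval[zero_se] <- ifelse(beta4[zero_se] == 0, 0, Inf)
    pv <- cap_p(2 * stats::pt(abs(tval), df = df, lower.tail = FALSE))
    singular <- !(ok0 & ok1)
    pv[singular] <- 1

    c0 <- safe_cor(Gr0[rows, , drop = FALSE], Mr0)
    c1 <- safe_cor(Gr1[rows, , drop = FALSE], Mr1)
    dif <- c1 - c0

    nm <- nrow(M)
    ng <- length(rows)
    res_list[[bi]] <- data.frame(
      metabolite_id = rep(rownames(M), each = ng),
      gene_id = rep(rownames(Gb), times = nm),
      beta1 = as.vector(beta1), beta2 = as.vector(beta2),
      beta3 = as.vector(beta3), beta4 = as.vector(beta4),
      se_beta4 = as.vector(se4), p_interaction = as.vector(pv),
      cor_group0 = as.vector(c0), cor_group1 = as.vector(c1),
      diff_corr = as.vector(dif), abs_diff_corr = abs(as.vector(dif)),
      singular = as.vector(singular),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res_list)
  # canonical row order (independent of block size): metabolite-major,
  # genes in input order within each metabolite
  out <- out[order(match(out$metabolite_id, rownames(M)),
                   match(out$gene_id, rownames(G))), , drop = FALSE]
  rownames(out) <- NULL
  bad <- out$singular
  out$beta1[bad] <- out$beta2[bad] <- out$beta3[bad] <- out$beta4[bad] <-
    out$se_beta4[bad] <- NA_real_
  if (any(bad))
    log_stage("integrate", "%d singular pair(s) reported with p = 1",
              sum(bad))
  out$fdr <- bh_fdr(out$p_interaction)
  attr(out, "model_count") <- model_count
  class(out) <- c("pair_results", class(out))
  out
}

#' Filter pair results down to the significant set
#'
#' Keeps pairs with `fdr <= fdr_max`, `|diff_corr| > min_abs_diff` and, if
#' `raw_p_max` is given, `p_interaction < raw_p_max`.  The raw-p screen is
#' off by default.
#'
#' @param results Data frame from [run_all_pairs()] (needs `fdr` and
#'   `diff_corr` columns).
#' @param fdr_max FDR ceiling (inclusive).
#' @param min_abs_diff Correlation-difference effect-size floor (exclusive).
#' @param raw_p_max Optional raw interaction p ceiling (exclusive).
#' @return The significant subset, same columns, with `significant = TRUE`.
#' @export
filter_significant <- function(results, fdr_max = 0.1, min_abs_diff = 0.1,
                               raw_p_max = NULL) {
  stopifnot(all(c("fdr", "diff_corr", "p_interaction") %in% names(results)))
  keep <- results$fdr <= fdr_max & abs(results$diff_corr) > min_abs_diff
  if (!is.null(raw_p_max)) keep <- keep & results$p_interaction < raw_p_max
  log_stage("filter", "fdr <= %g, |diff| > %g, raw p %s: %d -> %d pairs",
            fdr_max, min_abs_diff,
            if (is.null(raw_p_max)) "off" else paste("<", raw_p_max),
            nrow(results), sum(keep))
  out <- results[keep, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
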