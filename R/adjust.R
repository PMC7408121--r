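# Per-feature fixed-effect adjustment.  Nuisance covariates (pen, batch,
# RIN, age, and the phenotype NOT under test) are projected out of every
# feature by ordinary least squares; the adjusted value keeps the fitted
# intercept so values stay on an interpretable scale.

#' Specify an adjustment design
#'
#' @param fixed_factors Ordered character vector of categorical metadata
#'   columns (one-hot encoded, reference level dropped).
#' @param numeric_covariates Ordered character vector of numeric metadata
#'   columns (appended unscaled).
#' @param reference_levels Optional named character vector mapping a factor
#'   to its reference level; defaults to the lexically smallest level.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(fixed_factors = character(),
                        numeric_covariates = character(),
                        reference_levels = NULL) {
  all_cols <- c(fixed_factors, numeric_covariates)
  dup <- unique(all_cols[duplicated(all_cols)])
  if (length(dup))
    stop("column(s) listed twice in design: ", paste(dup, collapse = ", "),
         call. = FALSE)
  structure(list(fixed_factors = fixed_factors,
                 numeric_covariates = numeric_covariates,
                 reference_levels = reference_levels),
            class = "design_spec")
}

#' Standard nuisance designs for the two analysis modes
#'
#' In breed mode the phenotype under test is breed, so breed itself is kept
#' OUT of the adjustment and the feed-efficiency group is adjusted for; in
#' FE mode the roles swap.  Gene expression is additionally adjusted for
#' RIN and slaughter age; metabolite abundance for the metabolomics batch
#' and sampling age.  Pen is a nuisance factor for both layers.
#'
#' @param mode `"breed"` or `"fe"` — which phenotype the downstream
#'   integration will test.
#' @param layer `"genes"` or `"metabolites"`.
#' @return A [design_spec()].
#' @export
default_design <- function(mode = c("breed", "fe"),
                           layer = c("genes", "metabolites")) {
  mode <- match.arg(mode)
  layer <- match.arg(layer)
  other <- if (mode == "breed") "fe_group" else "breed"
  if (layer == "genes")
    design_spec(fixed_factors = c(other, "pen"),
                numeric_covariates = c("rin", "slaughter_age_days"))
  else
    design_spec(fixed_factors = c(other, "batch", "pen"),
                numeric_covariates = "sampling_age_days")
}

#' Build a design matrix from sample metadata
#'
#' Columns: intercept, then each fixed factor one-hot encoded with its
#' reference level dropped (factors in spec order, levels in sorted order),
#' then numeric covariates unscaled in spec order.  The design is checked
#' for full column rank.
#'
#' @param meta Sample metadata data frame (one row per sample).
#' @param spec A [design_spec()].
#' @return Numeric matrix (samples x coefficients) with row names
#'   `meta$sample_id`.
#' @export
build_design <- function(meta, spec) {
  stopifnot(inherits(spec, "design_spec"))
  validate_sample_table(meta)
  need <- c(spec$fixed_factors, spec$numeric_covariates)
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata lacks design column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(meta)
  cols <- list("(Intercept)" = rep(1, n))
  for (f in spec$fixed_factors) {
    v <- as.character(meta[[f]])
    lev <- sort(unique(v))
    if (length(lev) < 2L)
      stop("factor '", f, "' has a single level among these samples",
           call. = FALSE)
    ref <- if (!is.null(spec$reference_levels) &&
               f %in% names(spec$reference_levels)) {
      r <- spec$reference_levels[[f]]
      if (!r %in% lev)
        stop("reference level '", r, "' not found in factor '", f, "'",
             call. = FALSE)
      r
    } else lev[1L]
    for (l in setdiff(lev, ref))
      cols[[paste0(f, l)]] <- as.numeric(v == l)
  }
  for (cv in spec$numeric_covariates) {
    v <- meta[[cv]]
    if (!is.numeric(v))
      stop("covariate '", cv, "' is not numeric", call. = FALSE)
    cols[[cv]] <- v
  }
  X <- do.call(cbind, cols)
  rownames(X) <- meta$sample_id
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  X
}

#' Adjust an omics matrix for nuisance covariates
#'
#' Fits, per feature, an ordinary least-squares regression of the feature
#' values on the design matrix and returns `fitted intercept + residual`:
#' covariate and nuisance fixed effects are removed while the grand level
#' is preserved.  Residuals are orthogonal to every design column, so
#' adjusting twice is a no-op (projection).
#'
#' @param x An [omics_matrix()] (features x samples).
#' @param design Design matrix from [build_design()]; its rows must match
#'   the samples of `x` in the same order (never silently reordered).
#' @return An [omics_matrix()] with `layer_tag == "adjusted"` and a
#'   `residual_df` attribute (`n_samples - rank(design)`).
#' @export
adjust_covariates <- function(x, design) {
  stopifnot(inherits(x, "omics_matrix"), is.matrix(design))
  if (ncol(x) != nrow(design) ||
      !identical(colnames(x), rownames(design)))
    stop("design rows do not align with matrix samples; ",
         "expected identical IDs in identical order", call. = FALSE)
  n <- nrow(design)
  qrX <- qr(design)
  rdf <- n - qrX$rank
  if (rdf <= 0)
    stop("no residual degrees of freedom (n = ", n, ", rank = ",
         qrX$rank, ")", call. = FALSE)
  Y <- t(unclass(x))                      # samples x features
  coef <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  intercept <- if ("(Intercept)" %in% colnames(design))
    coef["(Intercept)", ] else rep(0, ncol(Y))
  adj <- t(resid + rep(intercept, each = n))
  out <- omics_matrix(adj, "adjusted")
  attr(out, "residual_df") <- rdf
  out
}
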