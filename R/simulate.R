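# Synthetic data with the statistical structure the analysis assumes:
# negative-binomial gene counts, log-normal metabolite abundances, nuisance
# covariates (pen, batch, age, RIN), an unbalanced two-group phenotype
# (12 vs 28 by default) and planted gene-metabolite pairs whose slope
# differs between the phenotype groups.

#' Simulation configuration
#'
#' Defaults emulate a two-breed pig muscle study at desk scale: 40 animals
#' in unbalanced groups of 12 and 28, negative-binomial counts with
#' dispersion 0.3 (between-animal biological variability typical of outbred
#' livestock), log-normal metabolite abundances with a two-level batch
#' shift, 8 pens and planted interaction pairs of slope difference 1.5 on
#' the log2-expression scale with residual noise 0.5.
#'
#' @param n_genes,n_metabolites,n_samples Feature and sample counts.
#' @param group_sizes Integer pair summing to `n_samples`; sizes of
#'   phenotype group 0 and group 1.
#' @param n_pens,n_batches Numbers of pen and metabolomics-batch levels.
#' @param nb_dispersion Negative-binomial dispersion: variance =
#'   mean + mean^2 * dispersion.
#' @param log_mean_range Interval (natural log scale) from which gene-wise
#'   mean counts are drawn log-uniformly.
#' @param noise_sd Residual standard deviation of planted metabolite models
#'   (log scale).
#' @param n_planted Number of planted gene-metabolite interaction pairs.
#' @param delta_slope Magnitude of the planted interaction coefficient
#'   (slope difference between the groups).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_metabolites = 200, n_samples = 40,
                       group_sizes = c(12, 28), n_pens = 8, n_batches = 2,
                       nb_dispersion = 0.3,
                       log_mean_range = log(c(50, 5000)),
                       noise_sd = 0.5, n_planted = 20, delta_slope = 1.5,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_metabolites = as.integer(n_metabolites),
              n_samples = as.integer(n_samples),
              group_sizes = as.integer(group_sizes),
              n_pens = as.integer(n_pens),
              n_batches = as.integer(n_batches),
              nb_dispersion = nb_dispersion,
              log_mean_range = log_mean_range,
              noise_sd = noise_sd,
              n_planted = as.integer(n_planted),
              delta_slope = delta_slope,
              seed = as.integer(seed))
  if (length(cfg$group_sizes) != 2L || sum(cfg$group_sizes) != cfg$n_samples)
    stop("group_sizes must be two integers summing to n_samples",
         call. = FALSE)
  if (any(cfg$group_sizes < 3L))
    stop("each phenotype group needs >= 3 samples", call. = FALSE)
  if (cfg$n_pens > cfg$n_samples)
    stop("n_pens cannot exceed n_samples", call. = FALSE)
  if (cfg$n_batches > cfg$n_samples)
    stop("n_batches cannot exceed n_samples", call. = FALSE)
  if (cfg$n_planted > cfg$n_genes * cfg$n_metabolites)
    stop("n_planted exceeds the number of gene-metabolite pairs",
         call. = FALSE)
  if (cfg$n_planted > min(cfg$n_genes, cfg$n_metabolites))
    stop("n_planted pairs use distinct genes and metabolites; reduce it ",
         "below min(n_genes, n_metabolites)", call. = FALSE)
  if (cfg$nb_dispersion <= 0 || cfg$noise_sd <= 0)
    stop("nb_dispersion and noise_sd must be positive", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Balanced-random assignment of n samples to k levels.
balanced_levels <- function(n, labels) {
  sample(rep_len(labels, n))
}

#' Simulate a paired transcriptome-metabolome dataset
#'
#' Generates gene counts, metabolite abundances, sample metadata, the
#' ground-truth list of planted pairs and a small pathway library (one set
#' collecting the planted metabolites plus random decoy sets).  For each
#' planted pair `(gene i, metabolite j)` the metabolite's log abundance is
#' rebuilt as `b1 + b2 * g + b3 * p + b4 * (g * p) + N(0, noise_sd)` where
#' `g` is the size-factor-normalized log2 expression of gene i and `p` is
#' the 0/1 phenotype, so the gene-metabolite slope differs by `b4` (equal
#' to `delta_slope` up to sign) between the groups.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `counts`, `abundances` (omics matrices),
#'   `meta` (data frame), `truth` (data frame of planted pairs with their
#'   coefficients plus attribute `enriched_set`), and `library`
#'   (a [pathway_library()]).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  met_ids <- sprintf("M%04d", seq_len(cfg$n_metabolites))

  phen <- rep(c(0L, 1L), times = cfg$group_sizes)
  meta <- data.frame(
    sample_id = samples,
    breed = c("duroc", "landrace")[phen + 1L],
    pen = balanced_levels(n, sprintf("pen%d", seq_len(cfg$n_pens))),
    batch = balanced_levels(n, sprintf("batch%d", seq_len(cfg$n_batches))),
    rin = round(stats::rnorm(n, 9, 0.4), 2),
    slaughter_age_days = round(stats::rnorm(n, 150, 6)),
    sampling_age_days = round(stats::rnorm(n, 140, 6)),
    fcr = round(stats::rnorm(n, 2.2, 0.25), 3),
    stringsAsFactors = FALSE
  )
  # a loosely phenotype-linked FE grouping (balanced within the dataset)
  meta$fe_group <- ifelse(meta$fcr <= stats::median(meta$fcr), "high", "low")

  # --- gene counts: NB with gene-wise means and mild covariate effects ----
  log_mu <- stats::runif(cfg$n_genes, cfg$log_mean_range[1L],
                         cfg$log_mean_range[2L])
  pen_eff <- stats::rnorm(cfg$n_pens, 0, 0.05)
  names(pen_eff) <- sprintf("pen%d", seq_len(cfg$n_pens))
  age_c <- meta$slaughter_age_days - mean(meta$slaughter_age_days)
  rin_c <- meta$rin - mean(meta$rin)
  sample_shift <- pen_eff[meta$pen] + 0.002 * age_c + 0.02 * rin_c
  mu <- exp(outer(log_mu, sample_shift, "+"))
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
    nrow = cfg$n_genes, dimnames = list(gene_ids, samples))
  counts <- omics_matrix(counts + 0, "counts")

  # --- metabolite abundances: log-normal with a batch shift --------------
  met_mu <- stats::runif(cfg$n_metabolites, log(1e4), log(1e6))
  met_sd <- stats::runif(cfg$n_metabolites, 0.2, 0.6)
  batch_eff <- stats::rnorm(cfg$n_batches, 0, 0.1)
  names(batch_eff) <- sprintf("batch%d", seq_len(cfg$n_batches))
  s_age_c <- meta$sampling_age_days - mean(meta$sampling_age_days)
  logm <- met_mu +
    matrix(stats::rnorm(cfg$n_metabolites * n, 0, met_sd),
           nrow = cfg$n_metabolites)
  logm <- sweep(logm, 2L, batch_eff[meta$batch] + 0.001 * s_age_c, "+")
  dimnames(logm) <- list(met_ids, samples)

  # --- planted phenotype-dependent pairs ---------------------------------
  if (cfg$n_planted > 0L) {
    planted_genes <- sample(gene_ids, cfg$n_planted)
    planted_mets <- sample(met_ids, cfg$n_planted)
    # base slopes of mixed sign so both direction clusters are populated
    b2 <- stats::rnorm(cfg$n_planted, 0.5, 0.1) *
      sample(c(-1, 1), cfg$n_planted, replace = TRUE)
    b4 <- cfg$delta_slope * sample(c(-1, 1), cfg$n_planted, replace = TRUE)
    b3 <- stats::rnorm(cfg$n_planted, 0, 0.2)
    gnorm <- normalize_counts(counts)
    for (k in seq_len(cfg$n_planted)) {
      g <- unclass(gnorm)[planted_genes[k], ]
      g <- g - mean(g)
      j <- planted_mets[k]
      logm[j, ] <- met_mu[match(j, met_ids)] + b2[k] * g + b3[k] * phen +
        b4[k] * g * phen + stats::rnorm(n, 0, cfg$noise_sd) +
        batch_eff[meta$batch]
    }
    truth <- data.frame(gene_id = planted_genes, metabolite_id = planted_mets,
                        beta2 = b2, beta3 = b3, beta4 = b4,
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(gene_id = character(), metabolite_id = character(),
                        beta2 = numeric(), beta3 = numeric(),
                        beta4 = numeric(), stringsAsFactors = FALSE)
  }
  abundances <- omics_matrix(exp(logm), "raw_abundance")

  # --- pathway library: planted set + random decoys ----------------------
  sets <- list()
  if (cfg$n_planted > 0L)
    sets$planted_set <- sort(unique(truth$metabolite_id))
  decoy_size <- max(3L, min(cfg$n_planted, cfg$n_metabolites %/% 4L))
  for (d in 1:5)
    sets[[sprintf("decoy_set%d", d)]] <- sort(sample(met_ids, decoy_size))
  attr(truth, "enriched_set") <- if (cfg$n_planted > 0L) "planted_set" else NA
  list(counts = counts, abundances = abundances, meta = meta, truth = truth,
       library = pathway_library(sets))
}

#' Simulate a null dataset (no planted pairs)
#'
#' Identical to [simulate_dataset()] with `n_planted` forced to 0; used as
#' a type-I-error harness.
#'
#' @param cfg A [sim_config()].
#' @return As [simulate_dataset()]; `truth` has zero rows.
#' @export
simulate_null <- function(cfg = sim_config()) {
  cfg$n_planted <- 0L
  simulate_dataset(cfg)
}
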