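---
title: "Phenotype-dependent gene–metabolite integration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-dependent gene–metabolite integration: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two omics layers are measured on the same animals: RNA-seq gene counts and
untargeted metabolite abundances. The question is not which genes or
metabolites differ between two phenotype groups (breed, or divergent feed
efficiency), but which gene–metabolite *relationships* differ — pairs whose
association flips or changes steeply between the groups. Such pairs point
at phenotype-specific co-regulation that neither layer shows alone.

## The per-pair model

After each layer is normalized and adjusted for nuisance covariates, every
gene–metabolite pair is fitted by ordinary least squares:

$$m = \beta_1 + \beta_2 g + \beta_3 p + \beta_4 (g \cdot p) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with $p \in \{0,1\}$ the phenotype. Because $p$ is binary, this is exactly
two group-wise simple regressions sharing one residual variance:
$\beta_2$ is the slope in group 0, $\beta_2+\beta_4$ the slope in group 1,
and $\beta_4$ the slope difference. The package exploits this: the blocked
engine computes per-group cross-products ($S_{xx}$, $S_{xy}$, $S_{yy}$)
once per gene/metabolite block and assembles every coefficient, residual
sum of squares and standard error in closed form — millions of models
without a single matrix factorization. The contract is not the algebra but
equality with a naive per-pair solver to 1e-10, which the tests enforce on
random instances, together with a canonical output ordering that is
independent of the block size.

The interaction p-value is the two-tailed t probability with $n-4$ degrees
of freedom. The phenotype is coded so that group 0 is Duroc (breed mode) or
the high-FE group (FE mode); the signed correlation difference
$r_1 - r_0$ then reads Landrace − Duroc or low − high. Published tables of
this quantity carry signed values under an "absolute difference" heading;
the signed convention reproduces their arithmetic exactly, and only the
effect-size screen takes the absolute value.

## Significance and clustering

- **FDR**: Benjamini–Hochberg across the *full* family of fitted pairs
  (matching the reported family sizes of ~6.8 million models). BH is
  written out explicitly and cross-checked against the reference
  implementation. The published cutoffs are FDR ≤ 0.1 and
  $|r_1 - r_0| > 0.1$.
- **Raw-p screen**: a stated cutoff of $p < 10^{-7}$ conflicts with
  published rows up to $4.3\times10^{-7}$; the screen is therefore exposed
  (`raw_p_max`) but off by default. With it off, the default filters retain
  every row of both published tables.
- **Clusters**: significant pairs are partitioned by the *sign of the
  reference-group correlation* (group 0). This reproduces the published
  7/14 split; keying on the sign of the difference instead is conceptually
  different (it would group by direction of change, not by direction of
  association) and is not used. An exactly-zero reference correlation — a
  measure-zero event on continuous data — goes deterministically to the
  anticorrelated cluster with a warning.
- **Display order**: cluster-major, then descending $|r_1 - r_0|$, ties by
  IDs. Note that the source study's figure captions name two "top" pairs
  that do not follow its own stated ranking; the package implements the
  stated rule and the tests assert only the internally consistent examples.

## Preprocessing decisions

- **Low-count filter**: "count < 1" is read as *total* count across
  samples < 1 — the only reading under which integer counts can be below
  one — i.e. all-zero genes; a per-sample-mean variant is available.
- **Normalization**: the upstream study delegates variance stabilization
  to an external tool. The stand-in here is median-of-ratios size factors
  (geometric-mean reference over zero-free genes) followed by
  $\log_2(x/s_j + 1)$ — monotone, variance-flattening, and fully specified
  within the package. It is *not* a re-implementation of any published
  tool's fit; this deviation is deliberate and documented.
- **Variance filter**: removes $\lceil f \cdot n\rceil$ lowest-variance
  features, ties broken by feature ID. This rounding is fixed because it
  reproduces both published retained counts (16,839 of 17,726 and 16,812
  of 17,697 at $f=0.05$) exactly.
- **RSD filter**: sample standard deviation (denominator $n-1$) over mean
  on the raw abundance scale, keep if > 0.15. The source does not state
  the denominator; $n-1$ is the package's fixed choice.
- **Negative-value screen**: drops any feature with a negative entry on
  the normalized/adjusted scale. Whether the original screen was
  feature-wise or sample-wise is unstated; feature-wise is implemented and
  flagged.
- **Phenotype classification**: FCR tails at mean ± k·sd within each breed
  stratum (k = 1); low FCR maps to the high-FE group, and the mapping is
  attached to the result so it is never implicit.

## Covariate adjustment

Each feature is regressed on a fixed-effect design (intercept; one-hot
factors with the lexically smallest reference level; unscaled numeric
covariates) by QR least squares, and the adjusted value is
*fitted intercept + residual*. Keeping the intercept holds values on an
interpretable scale so the negative-value screen remains meaningful; bare
residuals would center every feature at zero. Whether the original
workflow kept the intercept is unstated; the choice is explicit here and
the adjustment is a projection (adjusting twice changes nothing beyond
1e-10). The phenotype under test is never part of its own adjustment:
breed mode adjusts for the FE group (plus pen, RIN, slaughter age for
genes; batch, pen, sampling age for metabolites) and FE mode swaps breed
in. One caveat worth stating: adjusting the two layers with *different*
nuisance designs slightly distorts a cross-layer relationship (each
projection removes different components), which attenuates planted signal
in simulations. This is inherent to the two-stage design, not a defect of
the implementation; the package's recovery guarantees are therefore stated
for the integration engine on the scale where the signal lives.

## Over-representation and topology

The ORA p-value is the inclusive upper tail $P(X \ge k)$ of the
hypergeometric distribution — the exclusive tail is the classic silent
off-by-one — with sets intersected with the universe first and
zero-overlap sets reported at $p = 1$ exactly. The default universe is
everything that survived preprocessing in the relevant layer. No pathway
content is bundled (licensing and version drift); libraries arrive as GMT.
The optional topology score sums, over hit nodes, betweenness centrality
divided by the graph's maximum betweenness; `igraph` provides the exact
betweenness and the tests check it against a brute-force simple-path
enumeration on small graphs.

## The synthetic world

`simulate_dataset()` emulates the assumed structure of the real data at
desk scale, with defaults chosen once:

- 40 samples in groups of 12 and 28 (the study's breed split), 8 pens,
  2 metabolomics batches, RIN ~ N(9, 0.4), ages ~ N(150, 6)/N(140, 6).
- Counts: negative binomial with gene means log-uniform on [50, 5000] and
  dispersion 0.3 — between-animal biological variability typical of
  outbred livestock cohorts (BCV ≈ 0.55); mild pen/age/RIN effects on the
  log scale.
- Abundances: log-normal with per-metabolite log-sd 0.2–0.6 and a ±0.1
  batch shift. The real untargeted platform's raw scale is unpublished;
  log-normal is a stand-in, which is exactly why no acceptance value
  depends on the abundance scale.
- Planted pairs: the metabolite is rebuilt from the *normalized* gene as
  $\beta_1 + \beta_2 g + \beta_3 p + \beta_4 gp + N(0, 0.5)$ with
  $|\beta_4| = 1.5$ and base slopes $\beta_2$ of mixed sign (so both
  direction clusters are populated, as in real data). Metabolite is the
  response, matching the integration model's direction.

What a green test establishes: calibration of the interaction test (the
noise really is Gaussian, so type-I error is nominal by construction — the
test guards the engine, not nature), recovery of planted effects of the
stated size, and end-to-end plumbing. What it does not establish: behavior
under heavy-tailed abundances, count outliers, correlated genes,
confounded pens, or batch-phenotype imbalance — none of which the
generator produces.

## Numerical conventions

- Perfect fits underflow the t tail; p-values are capped at the smallest
  positive normalized double rather than reported as 0, keeping them in
  $(0, 1]$.
- Singular pairs (constant gene pooled or within a group) are reported
  with $p = 1$, NA coefficients and a `singular` flag — never an error —
  and degenerate within-group correlations are 0 with a flag.
- Matrix TSVs are written with 17 significant digits so the write/read
  cycle is bit-exact; missing values are rejected in matrices (the
  analysis assumes complete data).
- Spearman uses average ranks for ties (Pearson on ranks), making it
  invariant under strictly monotone transforms, which the tests check.

## Known limitations

Only binary phenotypes; covariates cannot enter the per-pair model (they
are handled upstream by design); no mixed models or empirical-Bayes
moderation; no bundled pathway knowledge; read-level RNA-seq processing
and mass-based metabolite annotation are upstream of this package's scope.
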