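# Independent oracles: deliberately naive implementations used only to
# check the package's vectorized/closed-form paths.

# OLS by explicit normal equations, with the interaction-term t test.
naive_pair_fit <- function(g, m, p) {
  X <- cbind(1, g, p, g * p)
  XtX <- t(X) %*% X
  beta <- drop(solve(XtX, t(X) %*% m))
  res <- m - drop(X %*% beta)
  df <- length(m) - 4L
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  se4 <- sqrt(covb[4L, 4L])
  tval <- unname(beta[4L]) / se4
  list(beta = unname(beta), se4 = unname(se4),
       p = unname(2 * stats::pt(abs(tval), df, lower.tail = FALSE)))
}

# Spearman as rank-then-Pearson, ranks and Pearson both written out.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Upper-tail hypergeometric by brute-force pmf summation.
naive_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Exact betweenness by enumerating all simple paths (tiny graphs only).
naive_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1L]] <<- path; return() }
      for (nb in nodes[adj[last, ]])
        if (!nb %in% path) walk(c(path, nb))
    }
    walk(s)
    out
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    ps <- paths_between(nodes[i], nodes[j])
    if (!length(ps)) next
    lens <- lengths(ps)
    shortest <- ps[lens == min(lens)]
    for (v in nodes)
      if (v != nodes[i] && v != nodes[j]) {
        thru <- sum(vapply(shortest, function(pp) v %in% pp, logical(1)))
        btw[v] <- btw[v] + thru / length(shortest)
      }
  }
  btw
}

# Small random fixture: omics matrices + metadata over n samples.
random_instance <- function(n_genes, n_mets, n = 20, seed = 1) {
  set.seed(seed)
  g <- matrix(rnorm(n_genes * n), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("S%02d", 1:n)))
  m <- matrix(rnorm(n_mets * n), n_mets,
              dimnames = list(sprintf("M%03d", 1:n_mets),
                              sprintf("S%02d", 1:n)))
  p <- rep(c(0L, 1L), length.out = n)
  meta <- data.frame(sample_id = colnames(g),
                     breed = c("duroc", "landrace")[p + 1L],
                     stringsAsFactors = FALSE)
  list(genes = omics_matrix(g, "adjusted"),
       metabolites = omics_matrix(m, "adjusted"),
       meta = meta, p = p)
}

toy_counts <- function(values, n_genes, n_samples,
                       genes = sprintf("g%d", seq_len(n_genes)),
                       samples = sprintf("s%d", seq_len(n_samples)),
                       layer = "counts") {
  omics_matrix(matrix(values, n_genes, n_samples,
                      dimnames = list(genes, samples)), layer)
}
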