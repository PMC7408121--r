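# Hypergeometric over-representation of a hit list against a set library,
# plus an optional topology score based on relative betweenness centrality.

#' Hypergeometric over-representation analysis
#'
#' For each set in the library, tests whether the hit list overlaps the set
#' more than expected by chance given the universe.  Sets are intersected
#' with the universe before testing; the p-value is the upper tail
#' `P(X >= n_overlap)` of `Hypergeometric(universe_size, set_size,
#' n_hits_total)` — note the inclusive tail, the classic off-by-one trap.
#' Zero-overlap sets get p = 1 exactly (`P(X >= 0) = 1`).  BH-FDR is
#' applied across the tested sets; raw p is kept as well.
#'
#' @param hits Character vector of hit feature IDs (must be a subset of
#'   `universe`).
#' @param universe Character vector: the background feature set (for
#'   metabolites, everything surviving preprocessing; for genes, all
#'   analyzed genes).
#' @param library A [pathway_library()].
#' @return Data frame with one row per set: `set_name`, `set_size` (within
#'   the universe), `universe_size`, `n_hits_total`, `n_overlap`, `p`,
#'   `fdr` and `impact` (NA unless topology graphs are supplied).
#' @export
hypergeom_ora <- function(hits, universe, library) {
  stopifnot(inherits(library, "pathway_library"))
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  strays <- setdiff(hits, universe)
  if (length(strays))
    stop("hit(s) not in the universe: ", paste(strays, collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  nh <- length(hits)
  rows <- lapply(names(library$sets), function(nm) {
    set_u <- intersect(library$sets[[nm]], universe)
    K <- length(set_u)
    k <- length(intersect(set_u, hits))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, nh, lower.tail = FALSE)
    impact <- if (!is.null(library$graphs) && nm %in% names(library$graphs))
      topology_impact(hits, library$graphs[[nm]]) else NA_real_
    data.frame(set_name = nm, set_size = K, universe_size = N,
               n_hits_total = nh, n_overlap = k, p = cap_p(p),
               impact = impact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    return(data.frame(set_name = character(), set_size = integer(),
                      universe_size = integer(), n_hits_total = integer(),
                      n_overlap = integer(), p = numeric(), fdr = numeric(),
                      impact = numeric()))
  out$fdr <- bh_fdr(out$p)
  out[, c("set_name", "set_size", "universe_size", "n_hits_total",
          "n_overlap", "p", "fdr", "impact")]
}

#' Relative-betweenness topology impact of a hit list
#'
#' Sums, over hit nodes, the node's betweenness centrality divided by the
#' maximum betweenness in the pathway graph (exact shortest-path counting).
#' Hit features absent from the graph contribute 0.  A graph in which every
#' node has zero betweenness (for example a complete graph) yields 0.
#'
#' @param hits Character vector of hit feature IDs.
#' @param edges Data frame of undirected edges with columns `from`, `to`.
#' @return Numeric impact score.
#' @export
topology_impact <- function(hits, edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (!nrow(edges)) stop("pathway graph has no edges", call. = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE)
  maxb <- max(btw)
  absent <- setdiff(unique(hits), names(btw))
  if (length(absent))
    log_stage("topology", "%d hit(s) absent from the graph contribute 0",
              length(absent))
  present <- intersect(unique(hits), names(btw))
  if (!length(present) || maxb == 0) return(0)
  sum(btw[present] / maxb)
}
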