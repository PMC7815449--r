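# Descriptive statistics of the recommendation networks.

#' Average degree of a network
#'
#' `2 * n_edges / n_nodes` for a simple undirected graph, unrounded (report
#' layers round to one decimal).
#'
#' @param network a [rec_network].
#' @return numeric.
#' @examples
#' # the provaccine search network: 283 nodes, 342 edges -> 2.417...
#' 2 * 342 / 283
#' @export
average_degree <- function(network) {
  stopifnot(inherits(network, "rec_network"))
  if (n_nodes(network) == 0L) stop("average degree is undefined for an empty network")
  2 * n_edges(network) / n_nodes(network)
}

#' Network diameter (largest connected component)
#'
#' Maximum finite unweighted shortest-path length.  Crawled networks can be
#' disconnected after cleaning, so the diameter is taken over the largest
#' connected component (by node count); a singleton or edgeless graph has
#' diameter 0.
#'
#' @param network a [rec_network].
#' @return integer.
#' @export
net_diameter <- function(network) {
  stopifnot(inherits(network, "rec_network"))
  if (n_nodes(network) == 0L) stop("diameter is undefined for an empty network")
  if (n_edges(network) == 0L) return(0L)
  g <- as_igraph(network)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == giant))
  as.integer(igraph::diameter(sub, directed = FALSE, weights = NA))
}

#' Average clustering coefficient
#'
#' Mean of local clustering coefficients over nodes.  By default nodes of
#' degree < 2 (whose neighbourhood has no pairs) contribute 0 and are
#' included in the mean — the convention of the network tool the descriptive
#' tables follow.  `include_low_degree = FALSE` averages over degree >= 2
#' nodes only.
#'
#' @param network a [rec_network].
#' @param include_low_degree logical; include degree < 2 nodes as zeros
#'   (default `TRUE`).
#' @return numeric in \[0, 1\]; 0 for an edgeless graph, `NaN` when
#'   `include_low_degree = FALSE` and no node has degree >= 2.
#' @export
average_clustering <- function(network, include_low_degree = TRUE) {
  stopifnot(inherits(network, "rec_network"))
  if (n_nodes(network) == 0L) stop("clustering is undefined for an empty network")
  g <- as_igraph(network)
  lc <- igraph::transitivity(g, type = "local", isolates = "NaN", weights = NA)
  if (include_low_degree) {
    lc[is.nan(lc)] <- 0
    mean(lc)
  } else {
    mean(lc, na.rm = TRUE)
  }
}

#' Global descriptive statistics of a network
#'
#' The per-network statistics of the descriptive table: node and edge
#' counts, average degree, diameter (largest component), average clustering
#' coefficient.
#'
#' @param network a [rec_network].
#' @inheritParams average_clustering
#' @return a `global_stats` list with fields `n_nodes`, `n_edges`,
#'   `average_degree`, `diameter`, `average_clustering`.
#' @export
global_stats <- function(network, include_low_degree = TRUE) {
  structure(
    list(
      n_nodes = n_nodes(network),
      n_edges = n_edges(network),
      average_degree = average_degree(network),
      diameter = net_diameter(network),
      average_clustering = average_clustering(network, include_low_degree)
    ),
    class = "global_stats"
  )
}

#' @export
print.global_stats <- function(x, ...) {
  cat(sprintf(paste0("Nodes %d | Edges %d | Avg degree %.1f | ",
                     "Diameter %d | Avg clustering %.3f\n"),
              x$n_nodes, x$n_edges, x$average_degree, x$diameter,
              x$average_clustering))
  invisible(x)
}
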