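# Network exposure model: a node's exposure to an attribute is the fraction
# of its ties leading to nodes that carry the attribute (diffusion of
# innovations; Valente's unweighted formulation).  E_i = (# neighbours with
# the attribute) / degree(i), with E_i = 0 for isolated nodes so that every
# node has a defined exposed/unexposed status.

#' Exposure of one node to an attribute
#'
#' The fraction of the node's neighbours satisfying the attribute predicate;
#' 0 for isolated nodes.  A node carrying the attribute itself is not
#' counted in its own exposure — only its neighbours matter.
#'
#' @param network a [rec_network].
#' @param node_id a node id present in the network.
#' @param attribute predicate (see [node_flags()]), e.g. `"stance=anti"`.
#' @return numeric in \[0, 1\].
#' @examples
#' # a node with 4 neighbours, 3 of which carry the attribute -> 0.75
#' ann <- data.frame(id = c("z", paste0("n", 1:4)),
#'                   vaccine_related = c(FALSE, TRUE, TRUE, TRUE, FALSE),
#'                   stance = c("none", "anti", "anti", "anti", "none"))
#' recs <- data.frame(src = "z", dst = paste0("n", 1:4))
#' node_exposure(build_network(recs, ann), "z", "stance=anti")
#' @export
node_exposure <- function(network, node_id, attribute) {
  if (!node_id %in% network$nodes$id)
    stop("unknown node id: ", node_id)
  network_exposure(network, attribute)$values[[node_id]]
}

#' Exposure of every node to an attribute
#'
#' Computes \eqn{E_i} for all nodes.  Neighbour counts are accumulated as
#' integers and divided by the degree only at the end, so the conservation
#' identity \eqn{\sum_i E_i \deg(i) = \sum_{a: attr(a)} \deg(a)} holds
#' exactly.
#'
#' @inheritParams node_exposure
#' @param weights optional named numeric vector of edge weights (Valente's
#'   weighted generalization); `NULL` (the default) uses unweighted
#'   adjacency, which is what the recommendation-network analysis assumes.
#'   When supplied, it must have one entry per edge row.
#' @return an `exposure_result`: list with `attribute` (label), `values`
#'   (named numeric vector over all node ids) and `n` (node count).
#' @export
network_exposure <- function(network, attribute, weights = NULL) {
  stopifnot(inherits(network, "rec_network"))
  f <- node_flags(network, attribute)
  ids <- network$nodes$id
  n <- length(ids)
  if (n == 0L) stop("empty network")
  ed <- network$edges
  if (is.null(weights)) {
    w <- rep(1L, nrow(ed))
  } else {
    if (length(weights) != nrow(ed))
      stop("weights must have one entry per edge")
    w <- as.numeric(weights)
  }
  num <- numeric(n); den <- numeric(n)
  names(num) <- names(den) <- ids
  if (nrow(ed)) {
    i <- c(ed$src, ed$dst)          # the node whose exposure accumulates
    j <- c(ed$dst, ed$src)          # its neighbour
    ww <- c(w, w)
    contrib <- ww * as.numeric(f[j])
    num_agg <- tapply(contrib, i, sum)
    den_agg <- tapply(ww, i, sum)
    num[names(num_agg)] <- num_agg
    den[names(den_agg)] <- den_agg
  }
  vals <- ifelse(den > 0, num / den, 0)
  structure(
    list(attribute = attr_label(attribute), values = vals, n = n),
    class = "exposure_result"
  )
}

#' @export
print.exposure_result <- function(x, ...) {
  s <- exposure_summary(x)
  cat(sprintf("<exposure_result> attribute %s over %d nodes\n",
              x$attribute, x$n))
  print(s)
  invisible(x)
}

#' Summary statistics of an exposure vector
#'
#' Mean and sample standard deviation (n - 1 denominator) of \eqn{E_i} over
#' all nodes, the number and percentage of exposed nodes (\eqn{E_i > 0}),
#' and the range of \eqn{E_i} over exposed nodes (`NA` bounds when no node
#' is exposed).  Values are unrounded; report layers round mean/SD to two
#' decimals and the percentage to one.
#'
#' @param result an `exposure_result` from [network_exposure()], or a bare
#'   numeric vector of exposures.
#' @return an `exposure_summary` list: `mean`, `sd`, `n`, `n_exposed`,
#'   `pct_exposed`, `range_over_exposed` (length-2 numeric).
#' @examples
#' exposure_summary(c(0.25, 0.5, 0, 1))  # mean 0.4375, 3 exposed
#' @export
exposure_summary <- function(result) {
  v <- if (inherits(result, "exposure_result")) result$values else as.numeric(result)
  if (length(v) == 0L) stop("empty exposure vector")
  exp_v <- v[v > 0]
  structure(
    list(
      mean = mean(v),
      sd = if (length(v) > 1L) sd(v) else 0,
      n = length(v),
      n_exposed = length(exp_v),
      pct_exposed = 100 * length(exp_v) / length(v),
      range_over_exposed = if (length(exp_v)) range(exp_v) else c(NA_real_, NA_real_)
    ),
    class = "exposure_summary"
  )
}

#' @export
print.exposure_summary <- function(x, ...) {
  rng <- if (is.na(x$range_over_exposed[1])) "-" else
    sprintf("%.2f-%.2f", x$range_over_exposed[1], x$range_over_exposed[2])
  cat(sprintf("  mean (SD) %.2f (%.2f); exposed %d (%.1f%%); range %s\n",
              x$mean, x$sd, x$n_exposed, x$pct_exposed, rng))
  invisible(x)
}

#' Exposed/unexposed status of every node
#'
#' A node is exposed when it has at least one neighbour carrying the
#' attribute (\eqn{E_i > 0}).  This binary flag is the case status of the
#' case-control analysis.
#'
#' @param result an `exposure_result` from [network_exposure()].
#' @return named logical vector over node ids.
#' @export
exposed_flags <- function(result) {
  stopifnot(inherits(result, "exposure_result"))
  result$values > 0
}
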