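# Core container: an undirected simple graph of annotated videos.

#' Annotation columns and their defaults
#'
#' Every node table carries these columns; absent columns are filled with the
#' defaults below (unannotated videos are treated as not vaccine-related,
#' stance "none", unknown source).
#'
#' @keywords internal
#' @noRd
.annotation_defaults <- function() {
  list(
    vaccine_related      = FALSE,
    stance               = "none",
    autism               = FALSE,
    health_related       = FALSE,
    health_misinformation = FALSE,
    source               = "unknown",
    language_excluded    = FALSE
  )
}

.stance_levels <- c("pro", "anti", "none")
.source_levels <- c("government", "academic_hospital", "pharma_forprofit",
                    "consumer", "news", "professional", "other", "unknown")
.provenance_levels <- c("search", "seed", "synthetic", "file")

#' Normalize a node annotation table
#'
#' Ensures the canonical columns exist with correct types; unknown values in
#' the enum columns are coerced to `"none"`/`"unknown"` with a warning unless
#' `strict = TRUE`, in which case they are an error.  Extra columns (e.g.
#' `views`, `likes`) are carried through untouched.
#'
#' @param nodes data.frame with at least an `id` column.
#' @param strict logical; upgrade recoverable annotation problems to errors.
#' @return data.frame with `id` first and all canonical annotation columns.
#' @keywords internal
#' @noRd
normalize_nodes <- function(nodes, strict = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes)) stop("node table must have an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (anyNA(nodes$id)) stop("node ids must not be NA")
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    if (strict) stop("duplicated node ids: ", paste(head(dup, 5), collapse = ", "))
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  }
  defs <- .annotation_defaults()
  for (col in names(defs)) {
    if (!col %in% names(nodes)) {
      nodes[[col]] <- rep(defs[[col]], nrow(nodes))
    }
  }
  for (col in c("vaccine_related", "autism", "health_related",
                "health_misinformation", "language_excluded")) {
    v <- nodes[[col]]
    if (is.character(v)) v <- tolower(v) %in% c("true", "t", "1", "yes")
    v <- as.logical(v)
    if (anyNA(v)) {
      if (strict) stop("non-boolean values in column '", col, "'")
      warning("unparseable values in '", col, "' defaulted to FALSE")
      v[is.na(v)] <- FALSE
    }
    nodes[[col]] <- v
  }
  st <- as.character(nodes$stance)
  bad <- is.na(st) | !st %in% .stance_levels
  if (any(bad)) {
    if (strict) stop("unknown stance values: ", paste(unique(st[bad]), collapse = ", "))
    warning(sum(bad), " unknown stance value(s) defaulted to 'none'")
    st[bad] <- "none"
  }
  nodes$stance <- st
  src <- as.character(nodes$source)
  bad <- is.na(src) | !src %in% .source_levels
  if (any(bad)) {
    if (strict) stop("unknown source values: ", paste(unique(src[bad]), collapse = ", "))
    warning(sum(bad), " unknown source value(s) defaulted to 'unknown'")
    src[bad] <- "unknown"
  }
  nodes$source <- src
  # stance != none only makes sense for vaccine-related videos
  off <- nodes$stance != "none" & !nodes$vaccine_related
  if (any(off)) {
    if (strict) stop("stance set on non-vaccine-related node(s): ",
                     paste(head(nodes$id[off], 5), collapse = ", "))
    warning(sum(off), " stance value(s) on non-vaccine-related nodes reset to 'none'")
    nodes$stance[off] <- "none"
  }
  # misinformation implies health-related
  off <- nodes$health_misinformation & !nodes$health_related
  if (any(off)) {
    if (strict) stop("health_misinformation without health_related: ",
                     paste(head(nodes$id[off], 5), collapse = ", "))
    nodes$health_related[off] <- TRUE
  }
  first <- c("id", names(defs))
  nodes[, c(first, setdiff(names(nodes), first)), drop = FALSE]
}

#' Construct a recommendation network object
#'
#' Low-level constructor for the `rec_network` class: an undirected simple
#' graph whose nodes are annotated videos.  Most users should build networks
#' with [build_network()] (which cleans raw records) or [simulate_crawl()];
#' this constructor validates an already-clean node/edge pair.
#'
#' @param nodes data.frame of node annotations with an `id` column; missing
#'   annotation columns are filled with defaults (see [build_network()]).
#' @param edges data.frame with columns `src`, `dst` and optionally `depth`
#'   (crawl level, provenance only) and `weight` (collapsed multiplicity).
#'   Must already be simple: no self-loops, no duplicate unordered pairs.
#' @param seed_ids character vector of start-node ids (subset of `nodes$id`).
#' @param provenance one of `"search"`, `"seed"`, `"synthetic"`, `"file"`.
#' @return An object of class `rec_network` with components `nodes`, `edges`,
#'   `seed_ids`, `provenance`.
#' @examples
#' net <- rec_network(
#'   nodes = data.frame(id = c("a", "b"), vaccine_related = c(TRUE, FALSE)),
#'   edges = data.frame(src = "a", dst = "b")
#' )
#' n_nodes(net)
#' @export
rec_network <- function(nodes, edges = NULL, seed_ids = character(),
                        provenance = "file") {
  nodes <- normalize_nodes(nodes)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(src = character(), dst = character(),
                        depth = integer(), weight = integer(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("src", "dst") %in% names(edges)))
    edges$src <- as.character(edges$src)
    edges$dst <- as.character(edges$dst)
    if (!"depth" %in% names(edges)) edges$depth <- NA_integer_
    if (!"weight" %in% names(edges)) edges$weight <- 1L
    edges <- edges[, c("src", "dst", "depth", "weight")]
    if (any(edges$src == edges$dst)) stop("self-loop in edge table")
    unknown <- setdiff(c(edges$src, edges$dst), nodes$id)
    if (length(unknown))
      stop("edge endpoint(s) not in node table: ",
           paste(head(unknown, 5), collapse = ", "))
    key <- paste(pmin(edges$src, edges$dst), pmax(edges$src, edges$dst))
    if (anyDuplicated(key)) stop("duplicate undirected edge(s) in edge table")
  }
  provenance <- match.arg(provenance, .provenance_levels)
  seed_ids <- as.character(seed_ids)
  if (length(bad <- setdiff(seed_ids, nodes$id)))
    seed_ids <- setdiff(seed_ids, bad)  # seeds dropped during cleaning stay out
  structure(
    list(nodes = nodes, edges = edges, seed_ids = seed_ids,
         provenance = provenance),
    class = "rec_network"
  )
}

#' @export
print.rec_network <- function(x, ...) {
  cat(sprintf("<rec_network> %d nodes, %d edges (provenance: %s, %d seeds)\n",
              n_nodes(x), n_edges(x), x$provenance, length(x$seed_ids)))
  comp <- table(factor(x$nodes$stance, levels = .stance_levels))
  cat(sprintf("  stance: pro %d, anti %d, none %d\n",
              comp[["pro"]], comp[["anti"]], comp[["none"]]))
  invisible(x)
}

#' Number of nodes / edges in a recommendation network
#' @param network a `rec_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) nrow(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Convert a recommendation network to an igraph object
#'
#' Nodes keep their ids as the igraph `name` attribute plus all annotation
#' columns; edges keep `depth` and `weight`.  The graph is undirected and
#' simple by construction.
#'
#' @param network a `rec_network`.
#' @return an undirected [igraph::igraph] graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "rec_network"))
  vert <- network$nodes
  names(vert)[names(vert) == "id"] <- "name"
  igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE, vertices = vert
  )
}

#' Node degrees of a recommendation network
#' @param network a `rec_network`.
#' @return named integer vector over all node ids (0 for isolated nodes).
#' @export
node_degrees <- function(network) {
  ids <- network$nodes$id
  deg <- integer(length(ids))
  names(deg) <- ids
  if (n_edges(network)) {
    t <- table(factor(c(network$edges$src, network$edges$dst), levels = ids))
    deg[] <- as.integer(t)
  }
  deg
}

#' Evaluate an attribute predicate over the nodes of a network
#'
#' Predicates select the attribute whose exposure (or case status) is being
#' measured.  Accepted forms:
#' \itemize{
#'   \item a character spec: terms joined by `&`, each term a logical column
#'     name (`"health_related"`), a negated column (`"!vaccine_related"`), or
#'     an equality on any column (`"stance=anti"`, `"source=news"`);
#'   \item a function taking the node data.frame and returning a logical
#'     vector;
#'   \item a logical vector named by node id (or unnamed, in node-table
#'     order).
#' }
#'
#' @param network a `rec_network`.
#' @param attribute predicate in one of the forms above.
#' @return named logical vector over all node ids.
#' @examples
#' net <- rec_network(data.frame(id = c("a", "b"),
#'                               vaccine_related = c(TRUE, FALSE),
#'                               stance = c("anti", "none")))
#' node_flags(net, "stance=anti")
#' node_flags(net, "!vaccine_related")
#' @export
node_flags <- function(network, attribute) {
  nodes <- network$nodes
  if (is.function(attribute)) {
    f <- attribute(nodes)
  } else if (is.logical(attribute)) {
    if (!is.null(names(attribute))) {
      if (!all(nodes$id %in% names(attribute)))
        stop("named flag vector does not cover all node ids")
      f <- unname(attribute[nodes$id])
    } else {
      if (length(attribute) != nrow(nodes))
        stop("unnamed flag vector length must equal node count")
      f <- attribute
    }
  } else if (is.character(attribute) && length(attribute) == 1L) {
    f <- rep(TRUE, nrow(nodes))
    for (term in strsplit(attribute, "&", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      neg <- startsWith(term, "!")
      if (neg) term <- trimws(substring(term, 2))
      if (grepl("=", term, fixed = TRUE)) {
        kv <- strsplit(term, "=", fixed = TRUE)[[1]]
        col <- trimws(kv[1]); val <- trimws(kv[2])
        if (!col %in% names(nodes)) stop("unknown attribute column: ", col)
        g <- as.character(nodes[[col]]) == val
      } else {
        if (!term %in% names(nodes)) stop("unknown attribute column: ", term)
        g <- as.logical(nodes[[term]])
      }
      g[is.na(g)] <- FALSE
      if (neg) g <- !g
      f <- f & g
    }
  } else {
    stop("attribute must be a character spec, function, or logical vector")
  }
  f[is.na(f)] <- FALSE
  names(f) <- nodes$id
  f
}

#' @keywords internal
#' @noRd
attr_label <- function(attribute) {
  if (is.character(attribute) && length(attribute) == 1L) attribute
  else "custom"
}
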