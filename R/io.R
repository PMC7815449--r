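# Readers and writers: GraphML, GEXF 1.2, CSV edge-list + node table.

.io_formats <- c("graphml", "gexf", "edgelist_csv")

#' Clean an edge table read from a file
#'
#' Drops self-loops (with a warning naming the offending ids), canonicalizes
#' endpoint order and merges duplicate undirected edges (weights summed,
#' minimum depth kept).
#' @keywords internal
#' @noRd
clean_edge_table <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(NULL)
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  if (!"depth" %in% names(edges)) edges$depth <- NA_integer_
  if (!"weight" %in% names(edges)) edges$weight <- 1L
  loops <- edges$src == edges$dst
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s) at node(s): ",
            paste(unique(edges$src[loops]), collapse = ", "))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!nrow(edges)) return(NULL)
  u <- pmin(edges$src, edges$dst)
  v <- pmax(edges$src, edges$dst)
  key <- paste(u, v, sep = "\r")
  dep <- suppressWarnings(
    tapply(as.numeric(edges$depth), key, function(x)
      if (all(is.na(x))) NA_integer_ else as.integer(min(x, na.rm = TRUE))))
  wt <- tapply(as.numeric(edges$weight), key, function(x) sum(x, na.rm = TRUE))
  ord <- !duplicated(key)
  k <- key[ord]
  data.frame(src = u[ord], dst = v[ord], depth = as.integer(dep[k]),
             weight = as.integer(wt[k]), stringsAsFactors = FALSE)
}

#' Read a recommendation network from a file
#'
#' Supported formats: GraphML (`"graphml"`), GEXF 1.2 (`"gexf"`), and a CSV
#' pair (`"edgelist_csv"`: `<stem>_edges.csv` with columns
#' `src,dst[,depth[,weight]]` and `<stem>_nodes.csv` with `id` plus attribute
#' columns).  Unknown attribute columns are carried through untouched;
#' self-loops and duplicate edges in the file are cleaned with a warning.
#'
#' @param path file path (for `edgelist_csv`, the stem or either CSV of the
#'   pair).
#' @param format one of `"graphml"`, `"gexf"`, `"edgelist_csv"`; guessed from
#'   the file extension when omitted.
#' @return a [rec_network].
#' @seealso [write_network()]
#' @export
read_network <- function(path, format = c("graphml", "gexf", "edgelist_csv")) {
  if (missing(format)) format <- guess_format(path)
  format <- match.arg(format)
  switch(format,
    graphml      = read_graphml(path),
    gexf         = read_gexf(path),
    edgelist_csv = read_edgelist_csv(path)
  )
}

#' Write a recommendation network to a file
#'
#' The write/read pair is the identity on node set, edge set and attribute
#' values for all three formats; booleans are serialized as `true`/`false`
#' in the XML formats.
#'
#' @param network a [rec_network].
#' @param path output path (for `edgelist_csv`, the stem: two files
#'   `<stem>_edges.csv` and `<stem>_nodes.csv` are written).
#' @param format one of `"graphml"`, `"gexf"`, `"edgelist_csv"`; guessed from
#'   the file extension when omitted.
#' @return `path`, invisibly.
#' @examples
#' net <- simulate_crawl(crawl_sim_config(n_seeds = 2, branching = 2,
#'                                        depth = 2, rng_seed = 1))$network
#' f <- tempfile(fileext = ".graphml")
#' write_network(net, f)
#' net2 <- read_network(f)
#' identical(net$edges[c("src", "dst")], net2$edges[c("src", "dst")])
#' @export
write_network <- function(network, path,
                          format = c("graphml", "gexf", "edgelist_csv")) {
  stopifnot(inherits(network, "rec_network"))
  if (missing(format)) format <- guess_format(path)
  format <- match.arg(format)
  switch(format,
    graphml      = write_graphml(network, path),
    gexf         = write_gexf(network, path),
    edgelist_csv = write_edgelist_csv(network, path)
  )
  invisible(path)
}

#' @keywords internal
#' @noRd
guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "" || ext == "csv") return("edgelist_csv")
  switch(ext,
    graphml = "graphml",
    gexf    = "gexf",
    stop("cannot guess network format from extension '.", ext,
         "'; pass format= explicitly")
  )
}

# ---- GraphML (via igraph) ---------------------------------------------------

write_graphml <- function(network, path) {
  net <- network
  # integer NA has no GraphML representation; store depth as double (NA -> NaN)
  net$edges$depth <- as.numeric(net$edges$depth)
  g <- as_igraph(net)
  g <- igraph::set_graph_attr(g, "provenance", network$provenance)
  g <- igraph::set_graph_attr(g, "seed_ids",
                              paste(network$seed_ids, collapse = ","))
  # igraph writes NA numeric attributes as NaN; acceptable, mapped back on read
  igraph::write_graph(g, path, format = "graphml")
}

read_graphml <- function(path) {
  g <- withCallingHandlers(
    igraph::read_graph(path, format = "graphml"),
    warning = function(w) {
      if (grepl("already an 'id' vertex attribute", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  va <- igraph::vertex_attr(g)
  ids <- if (!is.null(va$name)) as.character(va$name)
         else if (!is.null(va$id)) as.character(va$id)
         else as.character(seq_len(igraph::vcount(g)))
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (a in setdiff(names(va), c("name", "id")))
    nodes[[a]] <- va[[a]]
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- NULL
  if (nrow(el)) {
    ed <- data.frame(src = ids[el[, 1]], dst = ids[el[, 2]],
                     stringsAsFactors = FALSE)
    ea <- igraph::edge_attr(g)
    for (a in names(ea)) ed[[a]] <- ea[[a]]
    if ("depth" %in% names(ed)) {
      d <- ed$depth
      d[!is.finite(d) | abs(d) > .Machine$integer.max] <- NA
      ed$depth <- as.integer(d)
    }
    edges <- clean_edge_table(ed)
  }
  seed_ids <- character()
  ga <- igraph::graph_attr(g)
  if (!is.null(ga$seed_ids) && nzchar(ga$seed_ids))
    seed_ids <- strsplit(ga$seed_ids, ",", fixed = TRUE)[[1]]
  provenance <- if (!is.null(ga$provenance) &&
                    ga$provenance %in% .provenance_levels) ga$provenance
                else "file"
  rec_network(nodes, edges, seed_ids = seed_ids, provenance = provenance)
}

# ---- GEXF 1.2 (via xml2) ----------------------------------------------------
# No GEXF reader/writer ships with the installed graph stack, so the dialect
# is implemented here directly: typed node/edge attvalues, undirected edges,
# booleans as true/false.

.gexf_type <- function(v) {
  if (is.logical(v)) "boolean"
  else if (is.integer(v)) "integer"
  else if (is.numeric(v)) "double"
  else "string"
}

.gexf_fmt <- function(v) {
  if (is.logical(v)) ifelse(v, "true", "false") else as.character(v)
}

.gexf_parse <- function(x, type) {
  switch(type,
    boolean = tolower(x) %in% c("true", "1"),
    integer = {y <- suppressWarnings(as.integer(x)); y},
    long    = {y <- suppressWarnings(as.integer(x)); y},
    double  = suppressWarnings(as.numeric(x)),
    float   = suppressWarnings(as.numeric(x)),
    x
  )
}

write_gexf <- function(network, path) {
  nodes <- network$nodes
  edges <- network$edges
  nattr <- setdiff(names(nodes), "id")
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph",
                               defaultedgetype = "undirected",
                               mode = "static")
  atts <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (i in seq_along(nattr))
    xml2::xml_add_child(atts, "attribute", id = as.character(i - 1L),
                        title = nattr[i], type = .gexf_type(nodes[[nattr[i]]]))
  eatts <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eatts, "attribute", id = "d0", title = "depth",
                      type = "integer")
  nl <- xml2::xml_add_child(graph, "nodes")
  for (r in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nl, "node", id = nodes$id[r],
                              label = nodes$id[r])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (i in seq_along(nattr)) {
      val <- nodes[[nattr[i]]][r]
      if (!is.na(val))
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = .gexf_fmt(val))
    }
  }
  el <- xml2::xml_add_child(graph, "edges")
  for (r in seq_len(nrow(edges))) {
    e <- xml2::xml_add_child(el, "edge", id = as.character(r - 1L),
                             source = edges$src[r], target = edges$dst[r],
                             weight = as.character(edges$weight[r]))
    if (!is.na(edges$depth[r])) {
      av <- xml2::xml_add_child(e, "attvalues")
      xml2::xml_add_child(av, "attvalue", `for` = "d0",
                          value = as.character(edges$depth[r]))
    }
  }
  xml2::write_xml(doc, path)
}

read_gexf <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed GEXF file '", path,
                                           "': ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(graph, "xml_missing")) stop("malformed GEXF: no <graph> element")

  adefs <- xml2::xml_find_all(doc, ".//attributes[@class='node']/attribute")
  attr_title <- setNames(xml2::xml_attr(adefs, "title"),
                         xml2::xml_attr(adefs, "id"))
  attr_type  <- setNames(xml2::xml_attr(adefs, "type"),
                         xml2::xml_attr(adefs, "id"))
  edefs <- xml2::xml_find_all(doc, ".//attributes[@class='edge']/attribute")
  eattr_title <- setNames(xml2::xml_attr(edefs, "title"),
                          xml2::xml_attr(edefs, "id"))

  node_els <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(node_els, "id")
  if (anyNA(ids)) stop("malformed GEXF: <node> without id attribute")
  vals <- lapply(names(attr_title), function(aid) rep(NA_character_,
                                                      length(ids)))
  names(vals) <- names(attr_title)
  for (r in seq_along(node_els)) {
    avs <- xml2::xml_find_all(node_els[[r]], "./attvalues/attvalue")
    for (a in avs) {
      aid <- xml2::xml_attr(a, "for")
      if (aid %in% names(vals)) vals[[aid]][r] <- xml2::xml_attr(a, "value")
    }
  }
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (aid in names(vals))
    nodes[[attr_title[[aid]]]] <- .gexf_parse(vals[[aid]], attr_type[[aid]])

  edge_els <- xml2::xml_find_all(doc, ".//edges/edge")
  edges <- NULL
  if (length(edge_els)) {
    wt <- suppressWarnings(as.numeric(xml2::xml_attr(edge_els, "weight")))
    wt[is.na(wt)] <- 1
    depth <- rep(NA_integer_, length(edge_els))
    for (r in seq_along(edge_els)) {
      avs <- xml2::xml_find_all(edge_els[[r]], "./attvalues/attvalue")
      for (a in avs) {
        aid <- xml2::xml_attr(a, "for")
        if (!is.na(aid) && aid %in% names(eattr_title) &&
            eattr_title[[aid]] == "depth")
          depth[r] <- suppressWarnings(as.integer(xml2::xml_attr(a, "value")))
      }
    }
    edges <- data.frame(src = xml2::xml_attr(edge_els, "source"),
                        dst = xml2::xml_attr(edge_els, "target"),
                        depth = depth, weight = as.integer(wt),
                        stringsAsFactors = FALSE)
    if (anyNA(edges$src) || anyNA(edges$dst))
      stop("malformed GEXF: <edge> without source/target")
    edges <- clean_edge_table(edges)
  }
  rec_network(nodes, edges, provenance = "file")
}

# ---- CSV pair ---------------------------------------------------------------

.csv_stem <- function(path) {
  sub("(_edges|_nodes)?\\.csv$", "", path)
}

write_edgelist_csv <- function(network, path) {
  stem <- .csv_stem(path)
  write.csv(network$nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
  write.csv(network$edges, paste0(stem, "_edges.csv"), row.names = FALSE)
}

read_edgelist_csv <- function(path) {
  stem <- .csv_stem(path)
  nfile <- paste0(stem, "_nodes.csv")
  efile <- paste0(stem, "_edges.csv")
  if (!file.exists(nfile)) stop("node table not found: ", nfile)
  nodes <- read.csv(nfile, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
  edges <- NULL
  if (file.exists(efile)) {
    edges <- read.csv(efile, stringsAsFactors = FALSE,
                      colClasses = c(src = "character", dst = "character"))
    if (nrow(edges) == 0L) edges <- NULL else edges <- clean_edge_table(edges)
  }
  rec_network(nodes, edges, provenance = "file")
}
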