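# Construction and cleaning of annotated recommendation networks.

#' Build a clean recommendation network from raw crawl records
#'
#' Raw crawl output is a directed record list (video -> recommended video,
#' with the crawl depth at which the link was fetched) plus a node annotation
#' table.  This builder performs the cleaning the analysis assumes:
#' \itemize{
#'   \item repeated video ids collapse to one node;
#'   \item reciprocal and parallel directed records collapse to a single
#'     undirected edge (multiplicity kept as edge `weight`, minimum crawl
#'     level kept as edge `depth`; both are provenance metadata, unused by
#'     the exposure analysis);
#'   \item self-loops are dropped;
#'   \item nodes flagged `language_excluded` are removed together with their
#'     incident edges before any analysis.
#' }
#'
#' @param records data.frame of directed records with columns `src`, `dst`
#'   and optionally `depth`.  May be empty.
#' @param annotations data.frame of node annotations with an `id` column;
#'   missing annotation columns default (not vaccine-related, stance
#'   `"none"`, source `"unknown"`, all flags `FALSE`).  Record endpoints
#'   absent from the table get a default row with a warning, unless
#'   `strict = TRUE`.
#' @param seed_ids character vector of start-node ids, kept for provenance.
#' @param provenance one of `"search"`, `"seed"`, `"synthetic"`, `"file"`.
#' @param strict logical; if `TRUE`, an edge referencing an annotation-less
#'   id, or an unparseable annotation value, is an error naming the offender
#'   instead of a defaulted warning.
#' @return a [rec_network] object.
#' @examples
#' recs <- data.frame(src = c("a", "b", "a"), dst = c("b", "a", "b"))
#' ann  <- data.frame(id = c("a", "b"), vaccine_related = c(TRUE, FALSE))
#' net <- build_network(recs, ann)
#' n_nodes(net)  # 2
#' n_edges(net)  # 1: reciprocal + parallel records collapse
#' @export
build_network <- function(records, annotations, seed_ids = character(),
                          provenance = "file", strict = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) && !all(c("src", "dst") %in% names(records)))
    stop("records must have 'src' and 'dst' columns")
  annotations <- normalize_nodes(annotations, strict = strict)

  if (nrow(records)) {
    records$src <- as.character(records$src)
    records$dst <- as.character(records$dst)
    if (!"depth" %in% names(records)) records$depth <- NA_integer_
    missing_ids <- setdiff(unique(c(records$src, records$dst)), annotations$id)
    if (length(missing_ids)) {
      if (strict)
        stop("record endpoint(s) without annotation: ",
             paste(head(missing_ids, 10), collapse = ", "))
      warning(length(missing_ids),
              " record endpoint(s) without annotation given default annotations")
      extra <- normalize_nodes(data.frame(id = missing_ids,
                                          stringsAsFactors = FALSE))
      for (col in setdiff(names(annotations), names(extra)))
        extra[[col]] <- NA
      annotations <- rbind(annotations, extra[, names(annotations)])
    }
  }

  # language exclusion happens before network construction
  excluded <- annotations$id[annotations$language_excluded]
  annotations <- annotations[!annotations$language_excluded, , drop = FALSE]
  if (nrow(records) && length(excluded)) {
    keep <- !(records$src %in% excluded | records$dst %in% excluded)
    records <- records[keep, , drop = FALSE]
  }

  edges <- NULL
  if (nrow(records)) {
    loops <- records$src == records$dst
    if (any(loops)) {
      warning(sum(loops), " self-loop record(s) dropped")
      records <- records[!loops, , drop = FALSE]
    }
  }
  if (nrow(records)) {
    u <- pmin(records$src, records$dst)
    v <- pmax(records$src, records$dst)
    key <- paste(u, v, sep = "\r")
    ord <- !duplicated(key)
    depth <- suppressWarnings(
      tapply(as.numeric(records$depth), key, function(x)
        if (all(is.na(x))) NA_integer_ else as.integer(min(x, na.rm = TRUE)))
    )
    weight <- tapply(rep(1L, length(key)), key, sum)
    k <- key[ord]
    edges <- data.frame(src = u[ord], dst = v[ord],
                        depth = as.integer(depth[k]),
                        weight = as.integer(weight[k]),
                        stringsAsFactors = FALSE)
  }
  rec_network(annotations, edges, seed_ids = seed_ids,
              provenance = provenance)
}

#' Recode vaccine stance from the misinformation flag
#'
#' Harmonizes annotation batches coded under different schemes: a
#' vaccine-related video that contains misinformation is recoded as
#' antivaccine, any other vaccine-related video as provaccine, and
#' non-vaccine-related videos keep stance `"none"`.  Health flags are never
#' touched, and the rule never applies to non-vaccine-related videos even if
#' they carry misinformation.
#'
#' @param nodes a node annotation data.frame (or the `nodes` table of a
#'   `rec_network`), or a whole `rec_network`.
#' @param misinformation logical vector marking which videos contained
#'   misinformation; defaults to the `health_misinformation` column.
#' @return the input with its `stance` column recoded (a `rec_network` in,
#'   a `rec_network` out).
#' @examples
#' ann <- data.frame(id = c("a", "b", "c"),
#'                   vaccine_related = c(TRUE, TRUE, FALSE),
#'                   health_related = c(TRUE, FALSE, TRUE),
#'                   health_misinformation = c(TRUE, FALSE, TRUE))
#' recode_stance(ann)$stance  # "anti" "pro" "none"
#' @export
recode_stance <- function(nodes, misinformation = NULL) {
  if (inherits(nodes, "rec_network")) {
    nodes$nodes <- recode_stance(nodes$nodes, misinformation)
    return(nodes)
  }
  nodes <- normalize_nodes(nodes)
  if (is.null(misinformation)) misinformation <- nodes$health_misinformation
  stopifnot(length(misinformation) == nrow(nodes))
  misinformation[is.na(misinformation)] <- FALSE
  nodes$stance <- ifelse(!nodes$vaccine_related, "none",
                         ifelse(misinformation, "anti", "pro"))
  nodes
}
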