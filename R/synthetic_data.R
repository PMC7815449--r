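# Synthetic snowball-crawl generator with first-order category homophily.
#
# The real recommendation algorithm is proprietary and unobservable; the
# generator emulates only what the analysis depends on: breadth-first
# expansion with fixed branching and depth, deduplication-induced shrinkage
# (re-attachment to already-seen videos), and a parent->child category
# transition structure.

#' Default category space of the annotation scheme
#'
#' The partition implied by the annotation flags: vaccine-related videos are
#' pro- or antivaccine; non-vaccine videos are autism-related, health videos
#' with accurate content, health videos with misinformation, or other.
#' @return character vector of category names.
#' @export
sim_categories <- function() {
  c("provaccine", "antivaccine", "autism_nonvax",
    "health_accurate", "health_misinformation", "other")
}

#' Configuration of a synthetic recommendation-network crawl
#'
#' @param n_seeds positive integer; number of start videos (level 0).
#' @param branching positive integer; recommendations fetched per video
#'   (default 6, the number of related videos visible on one screen).
#' @param depth non-negative integer; number of expansion levels (default 3).
#' @param reattach_prob probability in \[0,1\] that a recommendation points to
#'   an already-generated video instead of a new one; this is what shrinks
#'   the node count below the no-reuse maximum `n_seeds * sum(branching^k)`.
#' @param category_transition row-stochastic matrix over categories:
#'   `H[p, c]` = P(new child has category c | parent has category p).
#'   Default: uniform rows over [sim_categories()].
#' @param seed_category_dist probability vector over categories for the
#'   level-0 videos.  Default: uniform.
#' @param source_dist optional list mapping category -> probability vector
#'   over source types (government, academic_hospital, ...); default picks
#'   plausible sources per category.
#' @param rng_seed integer seed; the whole simulation is reproducible from it.
#' @return a `crawl_sim_config` object (validated list).
#' @examples
#' cfg <- crawl_sim_config(n_seeds = 6, branching = 6, depth = 3,
#'                         reattach_prob = 0, rng_seed = 1)
#' sim <- simulate_crawl(cfg)
#' n_nodes(sim$network)  # 6 * (1 + 6 + 36 + 216) = 1554
#' @export
crawl_sim_config <- function(n_seeds, branching = 6L, depth = 3L,
                             reattach_prob = 0.4,
                             category_transition = NULL,
                             seed_category_dist = NULL,
                             source_dist = NULL,
                             rng_seed = 1L) {
  cats <- sim_categories()
  k <- length(cats)
  if (is.null(category_transition)) {
    category_transition <- matrix(1 / k, k, k, dimnames = list(cats, cats))
  }
  if (is.null(seed_category_dist)) {
    seed_category_dist <- setNames(rep(1 / k, k), cats)
  }
  if (is.null(source_dist)) source_dist <- default_source_dist()
  cfg <- structure(
    list(n_seeds = as.integer(n_seeds), branching = as.integer(branching),
         depth = as.integer(depth), reattach_prob = as.numeric(reattach_prob),
         category_transition = category_transition,
         seed_category_dist = seed_category_dist,
         source_dist = source_dist, rng_seed = as.integer(rng_seed)),
    class = "crawl_sim_config"
  )
  validate_config(cfg)
  cfg
}

#' @keywords internal
#' @noRd
validate_config <- function(cfg) {
  cats <- sim_categories()
  stopifnot(cfg$n_seeds >= 1L, cfg$branching >= 1L, cfg$depth >= 0L)
  if (cfg$reattach_prob < 0 || cfg$reattach_prob > 1)
    stop("reattach_prob must be in [0, 1]")
  H <- cfg$category_transition
  if (!is.matrix(H) || !identical(rownames(H), cats) ||
      !identical(colnames(H), cats))
    stop("category_transition must be a matrix with rows/cols named ",
         paste(cats, collapse = ", "))
  if (any(H < 0) || any(abs(rowSums(H) - 1) > 1e-9))
    stop("category_transition rows must be nonnegative and sum to 1")
  p <- cfg$seed_category_dist
  if (!identical(names(p), cats) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("seed_category_dist must be a probability vector over ",
         paste(cats, collapse = ", "))
  invisible(cfg)
}

#' @keywords internal
#' @noRd
default_source_dist <- function() {
  s <- function(...) {
    v <- c(...)
    setNames(v / sum(v), .source_levels)
  }
  # government, academic_hospital, pharma_forprofit, consumer, news,
  # professional, other, unknown
  list(
    provaccine            = s(40, 25, 2, 8, 20, 3, 1, 1),
    antivaccine           = s(0, 1, 1, 65, 30, 0, 2, 1),
    autism_nonvax         = s(5, 20, 1, 40, 30, 2, 1, 1),
    health_accurate       = s(20, 25, 3, 20, 28, 2, 1, 1),
    health_misinformation = s(0, 2, 3, 65, 27, 0, 2, 1),
    other                 = s(2, 3, 2, 45, 40, 2, 5, 1)
  )
}

#' Map simulator categories to annotation flags
#'
#' @param categories character vector of categories from [sim_categories()].
#' @param ids node ids.
#' @param sources character vector of source types (same length), optional.
#' @return node annotation data.frame.
#' @export
category_to_annotation <- function(categories, ids, sources = NULL) {
  stopifnot(all(categories %in% sim_categories()),
            length(ids) == length(categories))
  if (is.null(sources)) sources <- rep("unknown", length(ids))
  data.frame(
    id = as.character(ids),
    vaccine_related = categories %in% c("provaccine", "antivaccine"),
    stance = ifelse(categories == "provaccine", "pro",
                    ifelse(categories == "antivaccine", "anti", "none")),
    autism = categories == "autism_nonvax",
    health_related = categories %in% c("health_accurate",
                                       "health_misinformation"),
    health_misinformation = categories == "health_misinformation",
    source = sources,
    language_excluded = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate a snowball crawl of a recommendation network
#'
#' Breadth-first generation: level 0 consists of `n_seeds` start videos with
#' categories drawn from `seed_category_dist`; every video at level
#' `k < depth` emits `branching` recommendations.  Each recommendation
#' independently points back to a uniformly chosen already-generated video
#' with probability `reattach_prob` (creating cross-links and triangles, as
#' deduplication of a real crawl does), otherwise it creates a new video at
#' level `k + 1` whose category is drawn from the transition matrix row of
#' its parent's category.  The raw directed records are then cleaned into a
#' simple undirected [rec_network] via [build_network()].
#'
#' @param config a [crawl_sim_config()].
#' @return a `sim_result` list:
#' \describe{
#'   \item{network}{the cleaned [rec_network] (provenance `"synthetic"`).}
#'   \item{truth}{data.frame `id, category, level, parent_id, parent_category`
#'     (parent columns `NA` for seeds); covers every node.}
#'   \item{records}{the raw directed records with a `new_node` flag marking
#'     generative (non-reattachment) links.}
#'   \item{config}{the configuration used, including the transition matrix.}
#' }
#' The result is fully reproducible from `config$rng_seed` and leaves the
#' caller's RNG state untouched.
#' @export
simulate_crawl <- function(config) {
  validate_config(config)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(config$rng_seed)

  cats <- sim_categories()
  s <- config$n_seeds; b <- config$branching; d <- config$depth
  rho <- config$reattach_prob
  # upper bound on node count for id formatting
  n_id <- 0L
  new_id <- function() {
    n_id <<- n_id + 1L
    sprintf("v%06d", n_id)
  }

  ids <- character(0); category <- character(0); level <- integer(0)
  parent_id <- character(0); parent_cat <- character(0)
  for (i in seq_len(s)) {
    ids <- c(ids, new_id())
  }
  category <- sample(cats, s, replace = TRUE, prob = config$seed_category_dist)
  level <- rep(0L, s)
  parent_id <- rep(NA_character_, s)
  parent_cat <- rep(NA_character_, s)

  rec_src <- character(0); rec_dst <- character(0)
  rec_depth <- integer(0); rec_new <- logical(0)

  frontier <- seq_len(s)
  for (k in seq_len(d)) {
    next_frontier <- integer(0)
    for (p in frontier) {
      for (j in seq_len(b)) {
        if (runif(1) < rho && length(ids) > 0L) {
          tgt <- sample.int(length(ids), 1L)
          rec_src <- c(rec_src, ids[p]); rec_dst <- c(rec_dst, ids[tgt])
          rec_depth <- c(rec_depth, k); rec_new <- c(rec_new, FALSE)
        } else {
          child_cat <- sample(cats, 1L,
                              prob = config$category_transition[category[p], ])
          cid <- new_id()
          ids <- c(ids, cid)
          category <- c(category, child_cat)
          level <- c(level, k)
          parent_id <- c(parent_id, ids[p])
          parent_cat <- c(parent_cat, category[p])
          next_frontier <- c(next_frontier, length(ids))
          rec_src <- c(rec_src, ids[p]); rec_dst <- c(rec_dst, cid)
          rec_depth <- c(rec_depth, k); rec_new <- c(rec_new, TRUE)
        }
      }
    }
    frontier <- next_frontier
  }

  sources <- vapply(category, function(ct) {
    sd <- config$source_dist[[ct]]
    sample(names(sd), 1L, prob = sd)
  }, character(1))

  annotations <- category_to_annotation(category, ids, sources)
  records <- data.frame(src = rec_src, dst = rec_dst, depth = rec_depth,
                        new_node = rec_new, stringsAsFactors = FALSE)
  network <- suppressWarnings(
    build_network(records[, c("src", "dst", "depth")], annotations,
                  seed_ids = ids[seq_len(s)], provenance = "synthetic")
  )
  truth <- data.frame(id = ids, category = category, level = level,
                      parent_id = parent_id, parent_category = parent_cat,
                      stringsAsFactors = FALSE)
  structure(list(network = network, truth = truth, records = records,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> seed %d: ", x$config$rng_seed))
  print(x$network)
  invisible(x)
}

# ---- Presets mirroring the four study networks ------------------------------

# Per-network target composition over sim_categories(), read off the reported
# per-network category counts (vaccine-related split pro/anti; non-vaccine
# split autism / health-accurate / health-misinformation / other), plus the
# observed node count used to calibrate the re-attachment probability.
.preset_table <- function() {
  list(
    provaccine_search = list(
      n = 283, s = 6L, seed_mode = "search",
      counts = c(provaccine = 38, antivaccine = 3, autism_nonvax = 6,
                 health_accurate = 99, health_misinformation = 1,
                 other = 136)),
    antivaccine_search = list(
      n = 354, s = 6L, seed_mode = "search",
      counts = c(provaccine = 35, antivaccine = 5, autism_nonvax = 21,
                 health_accurate = 139, health_misinformation = 3,
                 other = 151)),
    conspiracy_seed = list(
      n = 483, s = 16L, seed_mode = "antivaccine",
      counts = c(provaccine = 34, antivaccine = 36, autism_nonvax = 13,
                 health_accurate = 157, health_misinformation = 110,
                 other = 133)),
    expert_seed = list(
      n = 551, s = 8L, seed_mode = "antivaccine",
      counts = c(provaccine = 15, antivaccine = 25, autism_nonvax = 22,
                 health_accurate = 172, health_misinformation = 144,
                 other = 173))
  )
}

#' Preset crawl scenarios for the four study networks
#'
#' Returns a ready-made [crawl_sim_config()] whose expected node count and
#' expected category composition match one of the four collected networks:
#' the two key-phrase search networks and the two seed networks (conspiracy
#' playlist, 16 seeds; antivaccine-expert playlist, 8 seeds).  All presets
#' use branching 6 and depth 3.  The re-attachment probability is solved
#' from the closed form `E[nodes] = s * (1 + q + q^2 + q^3)`, `q = b(1 - rho)`,
#' so that the expected node count equals the observed one.  The transition
#' matrix is `H = homophily * I + (1 - homophily) * outer(1, pi)` with `pi`
#' the network's category composition: child categories then have marginal
#' distribution `pi` at every level while parent-child category persistence
#' stays tunable.
#'
#' @param name one of `"provaccine_search"`, `"antivaccine_search"`,
#'   `"conspiracy_seed"`, `"expert_seed"`.
#' @param homophily mixing weight in \[0,1) of the identity component of the
#'   transition matrix (default 0.35).
#' @param rng_seed integer seed stored in the config.
#' @return a `crawl_sim_config`.
#' @examples
#' cfg <- preset_scenario("conspiracy_seed")
#' cfg$n_seeds    # 16
#' cfg$branching  # 6
#' @export
preset_scenario <- function(name = c("provaccine_search", "antivaccine_search",
                                     "conspiracy_seed", "expert_seed"),
                            homophily = 0.35, rng_seed = 1L) {
  name <- match.arg(name)
  stopifnot(homophily >= 0, homophily < 1)
  spec <- .preset_table()[[name]]
  cats <- sim_categories()
  pi <- spec$counts[cats] / sum(spec$counts)

  # solve s*(1+q+q^2+q^3) = n for q in (0, b], then rho = 1 - q/b
  target <- spec$n / spec$s
  f <- function(q) 1 + q + q^2 + q^3 - target
  q <- uniroot(f, c(1e-9, 6), tol = 1e-10)$root
  rho <- max(0, min(1, 1 - q / 6))

  H <- homophily * diag(length(cats)) +
    (1 - homophily) * matrix(pi, length(cats), length(cats), byrow = TRUE)
  dimnames(H) <- list(cats, cats)

  seed_dist <- if (spec$seed_mode == "antivaccine") {
    setNames(as.numeric(cats == "antivaccine"), cats)
  } else {
    setNames(as.numeric(pi), cats)
  }

  crawl_sim_config(n_seeds = spec$s, branching = 6L, depth = 3L,
                   reattach_prob = rho, category_transition = H,
                   seed_category_dist = seed_dist, rng_seed = rng_seed)
}

# ---- JSON config interchange ------------------------------------------------

#' Read / write a crawl configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_sim_config` returns a `crawl_sim_config`;
#'   `write_sim_config` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cats <- sim_categories()
  H <- as.matrix(x$category_transition)
  dimnames(H) <- list(cats, cats)
  crawl_sim_config(
    n_seeds = x$n_seeds, branching = x$branching, depth = x$depth,
    reattach_prob = x$reattach_prob, category_transition = H,
    seed_category_dist = setNames(as.numeric(x$seed_category_dist[cats]),
                                  cats),
    rng_seed = x$rng_seed
  )
}

#' @rdname read_sim_config
#' @param config a `crawl_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  validate_config(config)
  x <- list(
    n_seeds = config$n_seeds, branching = config$branching,
    depth = config$depth, reattach_prob = config$reattach_prob,
    category_transition = unclass(config$category_transition),
    seed_category_dist = as.list(config$seed_category_dist),
    rng_seed = config$rng_seed
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
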