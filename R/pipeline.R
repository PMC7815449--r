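# Annotation-stage utilities and end-to-end report generation.

#' Krippendorff's alpha (nominal level)
#'
#' Chance-corrected intercoder agreement via the coincidence-matrix
#' formulation: \eqn{\alpha = 1 - D_o / D_e}, where the observed
#' disagreement \eqn{D_o} accumulates, for every unit with \eqn{m_u \ge 2}
#' pairable values, each ordered pair of differing values with weight
#' \eqn{1/(m_u - 1)}, and the expected disagreement \eqn{D_e} is computed
#' from the value marginals.  Missing ratings are allowed; units with fewer
#' than two ratings are skipped.
#'
#' @param ratings a coders x units matrix (or data.frame) of nominal codes;
#'   `NA` marks a missing rating.  Values may be any atomic type — they are
#'   compared as categories.
#' @return alpha in (-1, 1]; 1 is perfect agreement, 0 chance-level.
#' @examples
#' m <- rbind(coder1 = c("a", "a", "b", "b"),
#'            coder2 = c("a", "a", "b", "b"))
#' krippendorff_alpha(m)  # 1
#' @export
krippendorff_alpha <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("alpha needs at least 2 coders and 2 units")
  vals <- sort(unique(as.vector(m[!is.na(m)])))
  k <- length(vals)
  if (k == 0L) stop("no pairable values")
  if (k == 1L) return(1)  # a single category: no disagreement is possible
  co <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in seq_len(ncol(m))) {
    x <- m[, u]
    x <- x[!is.na(x)]
    mu <- length(x)
    if (mu < 2L) next
    idx <- match(as.character(x), vals)
    tab <- tabulate(idx, nbins = k)
    # ordered pairs within the unit, weight 1/(mu - 1)
    pair <- outer(tab, tab) - diag(tab)
    co <- co + pair / (mu - 1)
  }
  n_c <- rowSums(co)
  n <- sum(n_c)
  if (n < 2) stop("insufficient pairable values for alpha")
  d_o <- sum(co) - sum(diag(co))
  d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

#' Systematic random sample of an ordered list
#'
#' Interval sampling with a seeded random start: the interval is
#' `k = round(1 / fraction)`, the start is uniform on `0 .. k-1`, and every
#' k-th item from the start is taken.  The sample size is within 1 of
#' `n * fraction` — e.g. a 10% reliability subsample of 538 items has 53 or
#' 54 items depending on the start.
#'
#' @param ids ordered vector of item ids.
#' @param fraction sampling fraction in (0, 1].
#' @param rng_seed integer seed for the random start.
#' @return subset of `ids`, in original order.
#' @export
systematic_sample <- function(ids, fraction, rng_seed = 1L) {
  n <- length(ids)
  if (n == 0L) stop("empty id list")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(ids)
  k <- max(1L, as.integer(round(1 / fraction)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(rng_seed)
  start <- sample.int(k, 1L) - 1L
  ids[seq(start + 1L, n, by = k)]
}

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up (not banker's): ties at
#' .5 always round away from zero, so 25/40 at 0 decimals is 63, not 62.
#' Composition tables print integer percentages; exposure tables one
#' decimal.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param decimals digits to keep (default 0).
#' @return numeric.
#' @examples
#' pct(25, 40)       # 63
#' pct(86, 551, 1)   # 15.6
#' @export
pct <- function(numerator, denominator, decimals = 0L) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Half-up rounding
#' @param x numeric vector.
#' @param decimals digits to keep.
#' @return numeric vector.
#' @export
round_half_up <- function(x, decimals = 0L) {
  f <- 10^decimals
  # 1e-9 guard absorbs binary representation error in exact .5 ties
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# ---- Report generation ------------------------------------------------------

.default_type_rows <- function() {
  list(
    nonvaccine       = "!vaccine_related",
    vaccine          = "vaccine_related",
    provaccine       = "stance=pro",
    antivaccine      = "stance=anti",
    autism           = "autism",
    health           = "health_related",
    health_accurate  = "health_related&!health_misinformation",
    health_misinfo   = "health_misinformation"
  )
}

#' Composition of a network by annotation category
#'
#' Counts and half-up percentages laid out like the descriptive table:
#' vaccine- vs non-vaccine-related (percent of all nodes), pro/anti split
#' (percent of vaccine-related nodes), sources of vaccine-related videos,
#' autism and health shares (percent of all nodes), accurate/misinformation
#' split (percent of health-related nodes).
#'
#' @param network a [rec_network].
#' @return data.frame with columns `row`, `count`, `pct`, `pct_base`.
#' @export
composition_table <- function(network) {
  nd <- network$nodes
  n <- nrow(nd)
  vax <- nd$vaccine_related
  n_vax <- sum(vax)
  health <- nd$health_related
  n_health <- sum(health)
  row <- function(name, count, base, base_label) {
    data.frame(row = name, count = count,
               pct = if (base > 0) pct(count, base) else NA_real_,
               pct_base = base_label, stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("nonvaccine_related", n - n_vax, n, "all"),
    row("vaccine_related", n_vax, n, "all"),
    row("provaccine", sum(nd$stance == "pro"), n_vax, "vaccine_related"),
    row("antivaccine", sum(nd$stance == "anti"), n_vax, "vaccine_related")
  )
  for (s in .source_levels) {
    out <- rbind(out, row(paste0("source_", s), sum(vax & nd$source == s),
                          n_vax, "vaccine_related"))
  }
  rbind(out,
        row("autism", sum(nd$autism), n, "all"),
        row("health_related", n_health, n, "all"),
        row("health_accurate",
            sum(health & !nd$health_misinformation), n_health,
            "health_related"),
        row("health_misinformation", sum(nd$health_misinformation),
            n_health, "health_related"))
}

#' Run the full exposure analysis and assemble a report bundle
#'
#' Orchestrates every stage in analysis order for each supplied network:
#' global statistics, category composition, per-node exposure to the target
#' attribute with its summary, and a case-control odds-ratio row per video
#' type with the selected confidence-interval method.  The bundle records
#' every convention in effect (clustering convention, CI method, rounding
#' mode) so printed numbers are auditable, and is deterministic: the same
#' inputs produce an identical bundle.
#'
#' @param networks named list of [rec_network] objects.
#' @param attribute exposure attribute predicate (default `"stance=anti"`,
#'   the headline analysis: exposure to antivaccine videos).
#' @param types named list of type predicates for the odds-ratio rows
#'   (default: the eight video-type rows of the published layout).
#' @param ci_method `"exact_conditional"` (default), `"woolf"`, or
#'   `"cornfield_approx"`; zero-cell tables always fall back to the exact
#'   conditional interval, recorded per row.
#' @param alpha significance level for the intervals.
#' @param include_low_degree clustering convention flag (see
#'   [average_clustering()]).
#' @return a `report_bundle`: per-network `global_stats`, `composition`,
#'   `exposure` (summary + values), `or_table` (data.frame), plus
#'   `conventions`.
#' @export
run_report <- function(networks, attribute = "stance=anti",
                       types = .default_type_rows(),
                       ci_method = c("exact_conditional", "woolf",
                                     "cornfield_approx"),
                       alpha = 0.05, include_low_degree = TRUE) {
  ci_method <- match.arg(ci_method)
  if (is.null(names(networks)) || any(!nzchar(names(networks))))
    stop("networks must be a named list")
  per_network <- lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    if (!inherits(net, "rec_network")) stop("not a rec_network: ", nm)
    if (n_nodes(net) == 0L) stop("empty network: ", nm)
    expo <- network_exposure(net, attribute)
    esum <- exposure_summary(expo)
    eflags <- exposed_flags(expo)
    rows <- lapply(names(types), function(ty) {
      tab <- withCallingHandlers(
        build_table(net, types[[ty]], eflags, type = ty),
        warning = function(w) invokeRestart("muffleWarning")
      )
      point <- tryCatch(odds_ratio(tab), error = function(e) NA_real_)
      zero_cell <- any(c(tab$a, tab$b, tab$c, tab$d) == 0L)
      method <- if (ci_method != "exact_conditional" && zero_cell)
        "exact_conditional" else ci_method
      ci <- tryCatch(or_ci(tab, method, alpha),
                     error = function(e) or_result(point, NA_real_, NA_real_,
                                                   method, alpha))
      data.frame(network = nm, type = ty, a = tab$a, b = tab$b, c = tab$c,
                 d = tab$d, or = point, ci_low = ci$ci_low,
                 ci_high = ci$ci_high, method = ci$method,
                 stringsAsFactors = FALSE)
    })
    list(
      global_stats = global_stats(net, include_low_degree),
      composition = composition_table(net),
      exposure_summary = esum,
      exposure_values = expo$values,
      or_table = do.call(rbind, rows)
    )
  })
  names(per_network) <- names(networks)
  structure(
    list(
      networks = per_network,
      conventions = list(
        attribute = attr_label(attribute),
        ci_method = ci_method,
        alpha = alpha,
        clustering_includes_low_degree = include_low_degree,
        diameter = "largest connected component",
        rounding = "half-up; composition 0 decimals, exposure 1 decimal",
        sd = "sample (n-1)"
      )
    ),
    class = "report_bundle"
  )
}

#' Write a report bundle to CSV and JSON
#'
#' Emits `<stem>_stats.csv`, `<stem>_composition.csv`, `<stem>_exposure.csv`
#' (one row per network, report-precision rounding), `<stem>_odds.csv`
#' (one row per network x type) and `<stem>.json` (the full bundle, rounded
#' the same way, plus the conventions block).
#'
#' @param bundle a `report_bundle` from [run_report()].
#' @param stem output path stem.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(bundle, stem) {
  stopifnot(inherits(bundle, "report_bundle"))
  nets <- names(bundle$networks)
  stats <- do.call(rbind, lapply(nets, function(nm) {
    g <- bundle$networks[[nm]]$global_stats
    data.frame(network = nm, n_nodes = g$n_nodes, n_edges = g$n_edges,
               average_degree = round_half_up(g$average_degree, 1),
               diameter = g$diameter,
               average_clustering = round_half_up(g$average_clustering, 3),
               stringsAsFactors = FALSE)
  }))
  comp <- do.call(rbind, lapply(nets, function(nm) {
    cbind(network = nm, bundle$networks[[nm]]$composition)
  }))
  expo <- do.call(rbind, lapply(nets, function(nm) {
    s <- bundle$networks[[nm]]$exposure_summary
    data.frame(network = nm,
               mean = round_half_up(s$mean, 2),
               sd = round_half_up(s$sd, 2),
               n_exposed = s$n_exposed,
               pct_exposed = round_half_up(s$pct_exposed, 1),
               n_unexposed = s$n - s$n_exposed,
               pct_unexposed = round_half_up(100 - s$pct_exposed, 1),
               range_low = s$range_over_exposed[1],
               range_high = s$range_over_exposed[2],
               stringsAsFactors = FALSE)
  }))
  odds <- do.call(rbind, lapply(nets, function(nm)
    bundle$networks[[nm]]$or_table))
  files <- paste0(stem, c("_stats.csv", "_composition.csv", "_exposure.csv",
                          "_odds.csv", ".json"))
  write.csv(stats, files[1], row.names = FALSE)
  write.csv(comp, files[2], row.names = FALSE)
  write.csv(expo, files[3], row.names = FALSE)
  write.csv(odds, files[4], row.names = FALSE)
  jsonlite::write_json(
    list(stats = stats, composition = comp, exposure = expo, odds = odds,
         conventions = bundle$conventions),
    files[5], auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(files)
}
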