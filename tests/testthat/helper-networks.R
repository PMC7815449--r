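# Shared fixture builders: all networks are generated in code.

# A star: one centre with `n_leaves` neighbours, `n_attr` of which carry
# stance = anti.
make_star <- function(n_leaves, n_attr, centre = "z") {
  leaves <- paste0("n", seq_len(n_leaves))
  ann <- data.frame(
    id = c(centre, leaves),
    vaccine_related = c(FALSE, seq_len(n_leaves) <= n_attr),
    stance = c("none", ifelse(seq_len(n_leaves) <= n_attr, "anti", "none")),
    stringsAsFactors = FALSE
  )
  recs <- data.frame(src = centre, dst = leaves, stringsAsFactors = FALSE)
  build_network(recs, ann)
}

# An Erdos-Renyi-style random annotated network built through the public
# constructor path, with anti stance assigned at rate `p_attr`.
random_network <- function(n, p_edge = 0.05, p_attr = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  recs <- data.frame(src = ids[pairs[keep, 1]], dst = ids[pairs[keep, 2]],
                     stringsAsFactors = FALSE)
  anti <- runif(n) < p_attr
  ann <- data.frame(id = ids, vaccine_related = anti,
                    stance = ifelse(anti, "anti", "none"),
                    stringsAsFactors = FALSE)
  build_network(recs, ann)
}

# Path graph on node ids p1..pn.
make_path <- function(n) {
  ids <- paste0("p", seq_len(n))
  recs <- if (n > 1)
    data.frame(src = ids[-n], dst = ids[-1], stringsAsFactors = FALSE)
  else data.frame(src = character(), dst = character())
  build_network(recs, data.frame(id = ids, stringsAsFactors = FALSE))
}

# Complete graph K_n.
make_complete <- function(n) {
  ids <- paste0("k", seq_len(n))
  pr <- t(combn(ids, 2))
  build_network(data.frame(src = pr[, 1], dst = pr[, 2]),
                data.frame(id = ids, stringsAsFactors = FALSE))
}

# Independent brute-force exposure oracle: explicit neighbour enumeration.
brute_force_exposure <- function(network, attribute) {
  f <- node_flags(network, attribute)
  ed <- network$edges
  vapply(network$nodes$id, function(v) {
    nb <- c(ed$dst[ed$src == v], ed$src[ed$dst == v])
    if (length(nb) == 0L) return(0)
    sum(f[nb]) / length(nb)
  }, numeric(1))
}

# Independent grid/bisection oracle for the exact conditional OR limits:
# direct choose() arithmetic (no logs), plain bisection on psi.
oracle_exact_limits <- function(a, b, c, d, alpha = 0.05) {
  n1 <- a + b; n2 <- c + d; m1 <- a + c
  lo <- max(0, m1 - n2); hi <- min(m1, n1)
  xs <- lo:hi
  tail_ge <- function(psi) {
    w <- choose(n1, xs) * choose(n2, m1 - xs) * psi^xs
    sum(w[xs >= a]) / sum(w)
  }
  tail_le <- function(psi) {
    w <- choose(n1, xs) * choose(n2, m1 - xs) * psi^xs
    sum(w[xs <= a]) / sum(w)
  }
  bisect <- function(fn, target, increasing) {
    lo_p <- 1e-12; hi_p <- 1e12
    for (i in 1:200) {
      mid <- sqrt(lo_p * hi_p)
      v <- fn(mid)
      up <- if (increasing) v < target else v > target
      if (up) lo_p <- mid else hi_p <- mid
    }
    sqrt(lo_p * hi_p)
  }
  low <- if (a == lo) 0 else bisect(tail_ge, alpha / 2, increasing = TRUE)
  high <- if (a == hi) Inf else bisect(tail_le, alpha / 2, increasing = FALSE)
  c(low = low, high = high)
}

# Independent Krippendorff alpha oracle: explicit enumeration of every
# ordered pair of ratings within each unit.
oracle_alpha <- function(ratings) {
  m <- as.matrix(ratings)
  pairs_x <- character(0); pairs_y <- character(0); wts <- numeric(0)
  for (u in seq_len(ncol(m))) {
    x <- m[, u]; x <- x[!is.na(x)]
    if (length(x) < 2) next
    for (i in seq_along(x)) for (j in seq_along(x)) if (i != j) {
      pairs_x <- c(pairs_x, as.character(x[i]))
      pairs_y <- c(pairs_y, as.character(x[j]))
      wts <- c(wts, 1 / (length(x) - 1))
    }
  }
  n_c <- tapply(wts, pairs_x, sum)
  n <- sum(wts)
  d_o <- sum(wts[pairs_x != pairs_y]) / n
  vals <- names(n_c)
  d_e <- 0
  for (cc in vals) for (kk in vals) if (cc != kk)
    d_e <- d_e + n_c[[cc]] * n_c[[kk]]
  d_e <- d_e / (n * (n - 1))
  1 - d_o / d_e
}
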