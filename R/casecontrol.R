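# Case-control odds ratios of exposure by video type.
#
# Orientation of the 2x2 table, fixed throughout:
#             exposed   unexposed
#   type T       a          b
#   not T        c          d
# OR = ad / bc measures how much more likely type-T videos are to be exposed
# to the target attribute than the other videos of the same network.

#' Construct a 2x2 exposed-by-type table
#'
#' @param a,b,c,d nonnegative counts: type-T exposed / type-T unexposed /
#'   other exposed / other unexposed.
#' @param type optional label for the type row.
#' @return a `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d, type = NULL) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be nonnegative integers")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d), type = type),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c(x$type %||% "type", "other"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Cross-tabulate video type against exposure status
#'
#' Builds the 2x2 table for one row of the odds-ratio report: videos
#' matching `type_predicate` against all other videos of the same network,
#' by exposed/unexposed status.  A predicate matching no node yields
#' `a = b = 0` with a warning (the odds ratio is then undefined and handled
#' downstream).
#'
#' @param network a [rec_network].
#' @param type_predicate predicate for the type row (see [node_flags()]).
#' @param exposed named logical vector over all node ids (from
#'   [exposed_flags()]).
#' @param type optional label; defaults to the predicate spelling.
#' @return a [two_by_two].
#' @export
build_table <- function(network, type_predicate, exposed, type = NULL) {
  stopifnot(inherits(network, "rec_network"))
  t_flag <- node_flags(network, type_predicate)
  ids <- network$nodes$id
  if (is.null(names(exposed))) {
    if (length(exposed) != length(ids))
      stop("unnamed exposed vector length must equal node count")
    names(exposed) <- ids
  }
  if (!all(ids %in% names(exposed)))
    stop("exposed status must cover all nodes")
  e <- exposed[ids]
  if (!any(t_flag))
    warning("type predicate '", attr_label(type_predicate),
            "' matches no node; odds ratio will be undefined")
  two_by_two(
    a = sum(t_flag & e), b = sum(t_flag & !e),
    c = sum(!t_flag & e), d = sum(!t_flag & !e),
    type = type %||% attr_label(type_predicate)
  )
}

#' Odds ratio of a 2x2 table
#'
#' `ad / bc`.  Zero-cell conventions: 0 when `a*d = 0` with `b*c > 0`,
#' `Inf` when `b*c = 0` with `a*d > 0`; no continuity correction is ever
#' applied silently.  When both products are 0 the odds ratio carries no
#' information and the call errors.
#'
#' @param table a [two_by_two].
#' @return nonnegative numeric, possibly `Inf`.
#' @examples
#' odds_ratio(two_by_two(10, 5, 2, 20))  # 20
#' odds_ratio(two_by_two(0, 3, 15, 265)) # 0
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  ad <- as.numeric(table$a) * table$d
  bc <- as.numeric(table$b) * table$c
  if (ad == 0 && bc == 0)
    stop("odds ratio undefined: both ad and bc are zero")
  if (bc == 0) return(Inf)
  ad / bc
}

#' @keywords internal
#' @noRd
or_result <- function(or_point, ci_low, ci_high, method, alpha) {
  structure(list(or_point = or_point, ci_low = ci_low, ci_high = ci_high,
                 method = method, alpha = alpha),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.4g (%.4g-%.4g), %d%% CI, method %s\n",
              x$or_point, x$ci_low, x$ci_high,
              round(100 * (1 - x$alpha)), x$method))
  invisible(x)
}

#' Woolf (log-OR) confidence interval
#'
#' Large-sample interval
#' \eqn{\exp(\log OR \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d})}.
#' Requires all cells positive; with a zero cell the log variance is
#' undefined and the call errors, directing the caller to [exact_ci()].
#'
#' @param table a [two_by_two].
#' @param alpha two-sided significance level (default 0.05).
#' @return an `or_result` (method `"woolf"`).
#' @export
woolf_ci <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "two_by_two"))
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0))
    stop("Woolf interval requires all cells > 0; use exact_ci() for zero cells")
  or <- odds_ratio(table)
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - alpha / 2)
  or_result(or, exp(log(or) - z * se), exp(log(or) + z * se),
            "woolf", alpha)
}

# ---- Noncentral (Fisher) hypergeometric machinery ---------------------------
# Conditional on all margins, the type-T-exposed count a follows Fisher's
# noncentral hypergeometric distribution with odds parameter psi.  Support:
# x in [max(0, m1 - n2), min(m1, n1)] with n1 = a+b, n2 = c+d, m1 = a+c.

#' @keywords internal
#' @noRd
nchg_logpmf <- function(x_support, n1, n2, m1, log_psi) {
  lw <- lchoose(n1, x_support) + lchoose(n2, m1 - x_support) +
    x_support * log_psi
  lw - max(lw)
}

#' @keywords internal
#' @noRd
nchg_tail <- function(a, n1, n2, m1, log_psi, lower = TRUE, midp = FALSE) {
  lo <- max(0L, m1 - n2); hi <- min(m1, n1)
  xs <- lo:hi
  w <- exp(nchg_logpmf(xs, n1, n2, m1, log_psi))
  w <- w / sum(w)
  p_at <- w[xs == a]
  if (lower) {
    p <- sum(w[xs <= a])
  } else {
    p <- sum(w[xs >= a])
  }
  if (midp) p <- p - 0.5 * p_at
  p
}

#' @keywords internal
#' @noRd
nchg_mean <- function(n1, n2, m1, log_psi) {
  lo <- max(0L, m1 - n2); hi <- min(m1, n1)
  xs <- lo:hi
  w <- exp(nchg_logpmf(xs, n1, n2, m1, log_psi))
  sum(xs * w) / sum(w)
}

#' Conditional maximum-likelihood estimate of the odds ratio
#'
#' Solves the conditional score equation \eqn{E_\psi[X] = a} for the odds
#' parameter of the noncentral hypergeometric distribution given the table
#' margins; 0 / `Inf` when `a` sits at the lower / upper end of the support.
#'
#' @param table a [two_by_two].
#' @return nonnegative numeric, possibly 0 or `Inf`.
#' @export
conditional_mle <- function(table) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; n1 <- table$a + table$b; n2 <- table$c + table$d
  m1 <- table$a + table$c
  lo <- max(0L, m1 - n2); hi <- min(m1, n1)
  if (a == lo && a == hi) stop("degenerate margins: support is a single point")
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  f <- function(lp) nchg_mean(n1, n2, m1, lp) - a
  exp(uniroot(f, c(-50, 50), tol = 1e-10)$root)
}

#' Exact conditional confidence interval for the odds ratio
#'
#' Equal-tail exact conditional limits obtained by inverting the noncentral
#' hypergeometric tail probabilities at level `alpha`: the lower limit
#' solves \eqn{P_\psi(X \ge a) = \alpha/2} and the upper limit solves
#' \eqn{P_\psi(X \le a) = \alpha/2}.  Usable with zero cells, which is
#' precisely when the large-sample intervals fail: `a = 0` gives a lower
#' limit of exactly 0 with a finite upper limit, and `b*c = 0` with
#' `a*d > 0` gives an infinite upper limit with a finite lower limit.
#'
#' @param table a [two_by_two].
#' @param alpha two-sided significance level (default 0.05).
#' @param midp logical; use the mid-P tail correction (less conservative,
#'   not guaranteed to cover at the nominal level).  Default `FALSE`.
#' @return an `or_result` (method `"exact_conditional"` or
#'   `"exact_conditional_midp"`).
#' @examples
#' exact_ci(two_by_two(0, 3, 15, 265))  # lower limit exactly 0
#' @export
exact_ci <- function(table, alpha = 0.05, midp = FALSE) {
  stopifnot(inherits(table, "two_by_two"), alpha > 0, alpha < 1)
  a <- table$a; n1 <- table$a + table$b; n2 <- table$c + table$d
  m1 <- table$a + table$c
  if (m1 == 0L || (table$b + table$d) == 0L)
    stop("degenerate margins: a column total is zero")
  if (n1 == 0L || n2 == 0L)
    stop("degenerate margins: a row total is zero")
  lo <- max(0L, m1 - n2); hi <- min(m1, n1)
  half <- alpha / 2
  bracket <- c(-80, 80)

  ci_low <- if (a == lo) 0 else {
    f <- function(lp) nchg_tail(a, n1, n2, m1, lp, lower = FALSE,
                                midp = midp) - half
    exp(uniroot(f, bracket, tol = 1e-12)$root)
  }
  ci_high <- if (a == hi) Inf else {
    f <- function(lp) nchg_tail(a, n1, n2, m1, lp, lower = TRUE,
                                midp = midp) - half
    exp(uniroot(f, bracket, tol = 1e-12)$root)
  }
  point <- tryCatch(odds_ratio(table), error = function(e) NA_real_)
  or_result(point, ci_low, ci_high,
            if (midp) "exact_conditional_midp" else "exact_conditional",
            alpha)
}

#' Cornfield approximate confidence interval
#'
#' Cornfield's iterative large-sample approximation to the exact conditional
#' limits: for a candidate odds ratio \eqn{\psi}, the fitted type-T-exposed
#' cell \eqn{A(\psi)} solves the margin-preserving quadratic
#' \eqn{A(n_2 - m_1 + A) / ((n_1 - A)(m_1 - A)) = \psi}; the limits are the
#' \eqn{\psi} at which the (optionally continuity-corrected) standardized
#' deviate \eqn{(a - A)/\sqrt{V(\psi)}} reaches \eqn{\pm z_{1-\alpha/2}},
#' with \eqn{1/V = 1/A + 1/(n_1-A) + 1/(m_1-A) + 1/(n_2-m_1+A)}.
#'
#' @param table a [two_by_two].
#' @param alpha two-sided significance level (default 0.05).
#' @param correction logical; apply the 0.5 continuity correction that makes
#'   the approximation track the exact limits (default `TRUE`).
#' @return an `or_result` (method `"cornfield_approx"`).
#' @export
cornfield_ci <- function(table, alpha = 0.05, correction = TRUE) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; n1 <- table$a + table$b; n2 <- table$c + table$d
  m1 <- table$a + table$c
  lo <- max(0L, m1 - n2); hi <- min(m1, n1)
  z <- qnorm(1 - alpha / 2)
  cc <- if (correction) 0.5 else 0

  fitted_cell <- function(psi) {
    if (abs(psi - 1) < 1e-12) {
      A <- n1 * m1 / (n1 + n2)
    } else {
      # psi*(n1-A)*(m1-A) = A*(n2-m1+A): quadratic in A
      qa <- 1 - psi
      qb <- n2 - m1 + psi * (n1 + m1)
      # clamp against catastrophic cancellation at extreme psi
      disc <- sqrt(max(qb^2 - 4 * qa * (-psi * n1 * m1), 0))
      A <- (-qb + disc) / (2 * qa)
      if (is.na(A) || !(A > lo && A < hi)) A <- (-qb - disc) / (2 * qa)
      if (is.na(A)) A <- hi
    }
    max(min(A, hi - 1e-9), lo + 1e-9)
  }
  deviate <- function(lp, sign) {
    A <- fitted_cell(exp(lp))
    V <- 1 / (1 / A + 1 / (n1 - A) + 1 / (m1 - A) + 1 / (n2 - m1 + A))
    (a - A - sign * cc) / sqrt(V)
  }
  # lower limit: A < a, (a - A - cc)/sqrt(V) = z; upper: A > a, mirrored
  ci_low <- if (a == lo) 0 else
    exp(uniroot(function(lp) deviate(lp, +1) - z, c(-80, 80),
                tol = 1e-10)$root)
  ci_high <- if (a == hi) Inf else
    exp(uniroot(function(lp) deviate(lp, -1) + z, c(-80, 80),
                tol = 1e-10)$root)
  point <- tryCatch(odds_ratio(table), error = function(e) NA_real_)
  or_result(point, ci_low, ci_high, "cornfield_approx", alpha)
}

#' Odds ratio with confidence interval, method dispatch
#'
#' @param table a [two_by_two].
#' @param method `"exact_conditional"` (default; works with zero cells),
#'   `"woolf"`, or `"cornfield_approx"`.
#' @param alpha two-sided significance level.
#' @return an `or_result`.
#' @export
or_ci <- function(table, method = c("exact_conditional", "woolf",
                                    "cornfield_approx"),
                  alpha = 0.05) {
  method <- match.arg(method)
  switch(method,
    exact_conditional = exact_ci(table, alpha),
    woolf             = woolf_ci(table, alpha),
    cornfield_approx  = cornfield_ci(table, alpha)
  )
}
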