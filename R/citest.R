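#' Configuration for the permutation CI test
#'
#' @param alpha significance level in (0, 1) used by callers that turn the
#'   p-value into a keep/remove decision (default 0.05).
#' @param B number of Monte-Carlo permutations (>= 1, default 1000; the
#'   smallest attainable p-value is 1 / (B + 1)).
#' @param seed optional integer seed; when non-NULL the test seeds the RNG
#'   itself, otherwise it consumes the caller's RNG stream.
#' @return a list of class `g4_ci_config`.
#' @export
ci_test_config <- function(alpha = 0.05, B = 1000L, seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(B), length(B) == 1L, B >= 1)
  structure(list(alpha = alpha, B = as.integer(B), seed = seed),
            class = "g4_ci_config")
}

# precompute integer level codes for the columns of a discrete data.frame;
# done once per dataset so repeated CI tests avoid refactoring columns
.ci_prep <- function(data, nodes = names(data)) {
  codes <- matrix(0L, nrow(data), length(nodes),
                  dimnames = list(NULL, nodes))
  nlev <- integer(length(nodes))
  for (j in seq_along(nodes)) {
    f <- factor(data[[nodes[j]]])
    codes[, j] <- as.integer(f)
    nlev[j] <- nlevels(f)
  }
  list(codes = codes, nlev = stats::setNames(nlev, nodes), n = nrow(data))
}

# 3-way count array (x levels, y levels, S strata) from precomputed codes
.ci_counts <- function(prep, x, y, S) {
  kx <- prep$nlev[[x]]; ky <- prep$nlev[[y]]
  cx <- prep$codes[, x]; cy <- prep$codes[, y]
  ks <- 1L
  cs <- rep(1L, prep$n)
  for (s in S) {
    cs <- cs + (prep$codes[, s] - 1L) * ks
    ks <- ks * prep$nlev[[s]]
  }
  counts <- tabulate(cx + kx * (cy - 1L) + (kx * ky) * (cs - 1L),
                     nbins = kx * ky * ks)
  dim(counts) <- c(kx, ky, ks)
  counts
}

# Pearson chi-squared of one stratum table; zero-margin cells contribute 0
.chi2_of_table <- function(tab) {
  rm_ <- rowSums(tab); cm_ <- colSums(tab); n <- sum(tab)
  if (n == 0) return(0)
  E <- outer(rm_, cm_) / n
  ok <- E > 0
  sum((tab[ok] - E[ok])^2 / E[ok])
}

# draw B tables with fixed margins (rm rows, cm cols) and return the B
# permutation chi-squared contributions of the stratum.  For tables with two
# rows (after transposition if needed) the multiple-hypergeometric row is
# sampled with vectorized rhyper(); general tables fall back to r2dtable().
.perm_chi2_stratum <- function(rm_, cm_, B) {
  if (length(rm_) > 2L && length(cm_) > 2L) {
    n <- sum(rm_)
    E <- as.vector(outer(rm_, cm_) / n)
    M <- matrix(unlist(stats::r2dtable(B, rm_, cm_), use.names = FALSE),
                ncol = B)
    return(colSums((M - E)^2 / E))
  }
  if (length(rm_) > 2L) { tmp <- rm_; rm_ <- cm_; cm_ <- tmp }
  n <- sum(rm_)
  k <- length(cm_)
  if (k == 2L) {
    # 2x2: all four |O - E| are equal, so chi2 is a closed form in n11
    E11 <- rm_[1] * cm_[1] / n
    E <- outer(rm_, cm_) / n
    n11 <- stats::rhyper(B, cm_[1], cm_[2], rm_[1])
    return((n11 - E11)^2 * sum(1 / E))
  }
  # sequentially sample row-1 counts across the k columns
  W <- matrix(0, B, k)
  remaining <- rep.int(rm_[1], B)
  totrem <- n
  for (j in seq_len(k - 1L)) {
    W[, j] <- stats::rhyper(B, cm_[j], totrem - cm_[j], remaining)
    remaining <- remaining - W[, j]
    totrem <- totrem - cm_[j]
  }
  W[, k] <- remaining
  E1 <- rm_[1] * cm_ / n
  E2 <- rm_[2] * cm_ / n
  O2 <- sweep(-W, 2L, cm_, "+")
  rowSums(sweep(sweep(W, 2L, E1)^2, 2L, E1, "/") +
            sweep(sweep(O2, 2L, E2)^2, 2L, E2, "/"))
}

# fast permutation p-value from precomputed codes; consumes the current RNG
.perm_ci_fast <- function(prep, x, y, S, B) {
  if (prep$nlev[[x]] < 2L || prep$nlev[[y]] < 2L)
    return(structure(1, statistic = 0, B = B, degenerate = TRUE))
  counts <- .ci_counts(prep, x, y, S)
  t_obs <- 0
  t_perm <- numeric(B)
  for (s in seq_len(dim(counts)[3])) {
    tab <- counts[, , s]
    n_s <- sum(tab)
    if (n_s == 0) next
    t_obs <- t_obs + .chi2_of_table(tab)
    rm_ <- rowSums(tab); cm_ <- colSums(tab)
    rm_ <- rm_[rm_ > 0]; cm_ <- cm_[cm_ > 0]
    if (length(rm_) < 2L || length(cm_) < 2L) next   # statistic constant 0
    t_perm <- t_perm + .perm_chi2_stratum(rm_, cm_, B)
  }
  exceed <- sum(t_perm >= t_obs - 1e-8 * max(1, t_obs))
  structure((1 + exceed) / (B + 1), statistic = t_obs, B = B)
}

#' Conditional Pearson chi-squared statistic
#'
#' For discrete variables `x`, `y` and a conditioning set `S`, sums the
#' two-way Pearson chi-squared statistic between `x` and `y` over every
#' configuration (stratum) of `S`, with expected counts formed from the
#' row/column margins within the stratum.  Strata (or margin levels) with
#' zero counts contribute nothing.
#'
#' @param data data.frame of discrete columns.
#' @param x,y column names, distinct and not in `S`.
#' @param S character vector of conditioning column names (possibly empty).
#' @return the statistic (a non-negative number).
#' @examples
#' d <- data.frame(a = rep(c("H", "L"), each = 20), b = rep(c("H", "L"), 20))
#' chi2_statistic(d, "a", "b")
#' @export
chi2_statistic <- function(data, x, y, S = character(0)) {
  if (nrow(data) == 0L) stop("empty data")
  stopifnot(x != y, !(x %in% S), !(y %in% S),
            all(c(x, y, S) %in% names(data)))
  counts <- .ci_counts(.ci_prep(data, unique(c(x, y, S))), x, y, S)
  sum(apply(counts, 3, .chi2_of_table))
}

#' Monte-Carlo permutation test of Pearson's chi-squared for conditional
#' independence
#'
#' Tests X independent of Y given S on discrete data.  The null distribution
#' is generated by permuting X's values within each configuration of S (which
#' preserves the conditional margins); each of the `B` permuted datasets is
#' re-tabulated and its conditional chi-squared computed, and
#' `p = (1 + #(T_b >= T_obs)) / (B + 1)`, so p lies in (0, 1].  Internally
#' the permuted tables are drawn directly from the fixed-margin (multiple
#' hypergeometric) distribution -- the exact distribution a within-stratum
#' shuffle of X induces on the contingency table -- at O(levels^2) per draw
#' instead of O(n).
#'
#' If `x` or `y` is constant the test returns p = 1 with a warning: a
#' degenerate variable carries no evidence of dependence.
#'
#' @inheritParams chi2_statistic
#' @param config a [ci_test_config()].
#' @return the p-value in (0, 1], with attributes `statistic` and `B`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = sample(c("H", "L"), 100, TRUE),
#'                 y = sample(c("H", "L"), 100, TRUE))
#' permutation_ci_test(d, "x", "y", config = ci_test_config(B = 199))
#' @export
permutation_ci_test <- function(data, x, y, S = character(0),
                                config = ci_test_config()) {
  if (nrow(data) == 0L) stop("empty data")
  stopifnot(inherits(config, "g4_ci_config"),
            x != y, !(x %in% S), !(y %in% S),
            all(c(x, y, S) %in% names(data)))
  if (!is.null(config$seed)) set.seed(config$seed)
  prep <- .ci_prep(data, unique(c(x, y, S)))
  p <- .perm_ci_fast(prep, x, y, S, config$B)
  if (isTRUE(attr(p, "degenerate")))
    warning("'", if (prep$nlev[[x]] < 2L) x else y,
            "' is constant; returning p = 1", call. = FALSE)
  p
}
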