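#' N-of-M average model
#'
#' Consensus of a list of candidate networks: an adjacency is kept iff it
#' appears (in either orientation or undirected) in at least `N` candidates.
#' The orientation of a kept adjacency is the plurality vote among the
#' candidates containing it (directed one way, the other way, or
#' undirected); ties go undirected.
#'
#' @param candidates non-empty list of `g4_pdag` objects over one node set.
#' @param N agreement threshold, `1 <= N <= length(candidates)`.
#' @return a `g4_pdag`.
#' @export
average_model <- function(candidates, N) {
  stopifnot(length(candidates) >= 1L, N >= 1L, N <= length(candidates))
  nodes <- candidates[[1]]$nodes
  p <- length(nodes)
  fwd <- matrix(0L, p, p, dimnames = list(nodes, nodes))  # votes for i -> j
  und <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (g in candidates) {
    stopifnot(setequal(g$nodes, nodes))
    a <- g$amat[nodes, nodes]
    fwd <- fwd + (a == 1L & t(a) == 0L)
    und <- und + (a == 1L & t(a) == 1L)
  }
  support <- fwd + t(fwd) + und
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (support[i, j] < N) next
      votes <- c(fwd[i, j], fwd[j, i], und[i, j])
      top <- which(votes == max(votes))
      if (length(top) > 1L || top == 3L) {
        amat[i, j] <- amat[j, i] <- 1L
      } else if (top == 1L) {
        amat[i, j] <- 1L
      } else {
        amat[j, i] <- 1L
      }
    }
  }
  pdag_from_amat_checked(amat)
}

#' Accuracy and coverage of candidates against a consensus network
#'
#' For each candidate c: accuracy_c = |E_c intersect E_cons| / |E_c| (1 when
#' the candidate has no edges) and coverage_c = |E_c intersect E_cons| /
#' |E_cons| (1 when the consensus has no edges); the function returns the
#' means over candidates.  Edge membership is compared at the skeleton
#' (adjacency) level by default; `directed = TRUE` requires the orientation
#' status to match too.
#'
#' @param candidates list of `g4_pdag`.
#' @param consensus a `g4_pdag`.
#' @param directed match orientations as well as adjacencies?
#' @return named numeric vector `c(accuracy =, coverage =)`.
#' @export
accuracy_coverage <- function(candidates, consensus, directed = FALSE) {
  cons_keys <- .edge_id_set(consensus, directed)
  per <- vapply(candidates, function(g) {
    keys <- .edge_id_set(g, directed)
    hit <- length(intersect(keys, cons_keys))
    c(if (length(keys)) hit / length(keys) else 1,
      if (length(cons_keys)) hit / length(cons_keys) else 1)
  }, numeric(2))
  c(accuracy = mean(per[1, ]), coverage = mean(per[2, ]))
}

# identifiers of a graph's edges; directed matching distinguishes x->y, y->x
# and x--y, skeleton matching collapses them
.edge_id_set <- function(g, directed) {
  if (!directed) return(edge_keys(skeleton_edges(g)))
  d <- directed_edges(g)
  u <- undirected_edges(g)
  c(if (nrow(d)) paste0(d[, 1], ">", d[, 2]),
    if (nrow(u)) paste0(u[, 1], "-", u[, 2]))
}

#' Robustness AUC of a coverage-vs-accuracy curve
#'
#' Sorts the points by accuracy and integrates coverage over accuracy with
#' the trapezoidal rule, normalized by the spanned accuracy range so the
#' result lies in [0, 1] whenever coverage does.  Note the normalization
#' makes this a scale-free comparative index, not an absolute area.
#'
#' @param points data.frame (or matrix) with columns `accuracy` and
#'   `coverage`; at least two distinct accuracy values are required.
#' @return the normalized AUC.
#' @export
robustness_auc <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("accuracy", "coverage") %in% names(points)),
            nrow(points) >= 2L)
  o <- order(points$accuracy, points$coverage)
  x <- points$accuracy[o]; y <- points$coverage[o]
  span <- x[length(x)] - x[1]
  if (span <= 0) stop("all points share one accuracy; AUC is degenerate")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / span
}

#' Pick the agreement threshold N closest to perfect robustness
#'
#' The operating N is the one whose (accuracy, coverage) point lies nearest
#' the upper-right corner (1, 1) in Euclidean distance (ties: smaller N).
#'
#' @param record data.frame with columns `N`, `acc_mean`, `cov_mean` (one
#'   strategy/size at a time).
#' @return the selected N (integer).
#' @export
select_N <- function(record) {
  stopifnot(all(c("N", "acc_mean", "cov_mean") %in% names(record)))
  d <- sqrt((1 - record$acc_mean)^2 + (1 - record$cov_mean)^2)
  record$N[order(d, record$N)][1]
}

#' Bootstrap trials of stratified sampling plus structure learning
#'
#' Runs the full robustness protocol: per trial, draw `n_sample_sets`
#' stratified samples, learn one candidate network from each, and form the
#' N-of-`n_sample_sets` average model for every N in `N_grid`; accuracy and
#' coverage of the candidates are measured against the same trial's average
#' model at the same N.  Means and standard deviations are aggregated over
#' `n_trials` trials, and an AUC summarizes each strategy/size.  All
#' randomness derives from `master_seed` (one sampling seed and one
#' permutation-test seed per trial x sample set), so a rerun with the same
#' arguments is bit-identical.
#'
#' @param table discrete table with a `stratum` column (see [discretize()]
#'   or [simulate_observations()]).
#' @param config a [sampling_config()]; its `seed` field is ignored here.
#' @param n_sample_sets candidate networks per trial (default 10).
#' @param n_trials number of trials (default 50).
#' @param N_grid agreement thresholds to evaluate (default `1:n_sample_sets`).
#' @param ci_config a [ci_test_config()] for the CI test inside
#'   [pc_stable()].
#' @param max_cond maximum conditioning-set size (see [pc_stable()]).
#' @param master_seed integer master seed.
#' @param directed match edges by orientation in accuracy/coverage?
#' @return list with `record` (data.frame: strategy, k, N, acc_mean, acc_sd,
#'   cov_mean, cov_sd), `auc`, `average_models` (list indexed `[[N]][[trial]]`)
#'   and `candidates` (list indexed `[[trial]][[set]]`).
#' @export
run_trials <- function(table, config, n_sample_sets = 10L, n_trials = 50L,
                       N_grid = seq_len(n_sample_sets),
                       ci_config = ci_test_config(),
                       max_cond = NULL, master_seed = 1L,
                       directed = FALSE) {
  stopifnot(inherits(config, "g4_sampling_config"),
            all(N_grid >= 1L), all(N_grid <= n_sample_sets))
  set.seed(master_seed)
  samp_seeds <- matrix(sample.int(.Machine$integer.max, n_trials * n_sample_sets),
                       n_trials, n_sample_sets)
  perm_seeds <- matrix(sample.int(.Machine$integer.max, n_trials * n_sample_sets),
                       n_trials, n_sample_sets)

  acc <- cov <- matrix(NA_real_, n_trials, length(N_grid))
  avg_models <- lapply(N_grid, function(N) vector("list", n_trials))
  names(avg_models) <- as.character(N_grid)
  cands <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    candidates <- vector("list", n_sample_sets)
    for (j in seq_len(n_sample_sets)) {
      cfg <- config; cfg$seed <- samp_seeds[t, j]
      smp <- stratified_sample(table, cfg)
      fit <- pc_stable(smp,
                       config = ci_test_config(alpha = ci_config$alpha,
                                               B = ci_config$B,
                                               seed = perm_seeds[t, j]),
                       max_cond = max_cond)
      candidates[[j]] <- fit$graph
    }
    cands[[t]] <- candidates
    for (b in seq_along(N_grid)) {
      m <- average_model(candidates, N_grid[b])
      avg_models[[b]][[t]] <- m
      ac <- accuracy_coverage(candidates, m, directed = directed)
      acc[t, b] <- ac[["accuracy"]]
      cov[t, b] <- ac[["coverage"]]
    }
  }
  record <- data.frame(
    strategy = config$strategy, k = config$k, N = N_grid,
    acc_mean = colMeans(acc), acc_sd = apply(acc, 2, stats::sd),
    cov_mean = colMeans(cov), cov_sd = apply(cov, 2, stats::sd))
  auc <- tryCatch(
    robustness_auc(data.frame(accuracy = record$acc_mean,
                              coverage = record$cov_mean)),
    error = function(cnd) NA_real_)
  list(record = record, auc = auc, average_models = avg_models,
       candidates = cands)
}

#' Common network across trials
#'
#' Intersects the skeletons of the per-trial average models and attaches a
#' direction frequency to every surviving adjacency: among the contributing
#' models, an x -> y orientation counts 1, y -> x counts 0 and undirected
#' counts 1/2, and the frequency is the mean (so a fully undirected edge sits
#' at 0.5).
#'
#' @param average_models non-empty list of `g4_pdag` (one per trial, at the
#'   chosen N).
#' @return an object of class `g4_consensus`: list with `nodes` and `edges`
#'   (data.frame `from`, `to`, `freq_forward`, `n_models`; `from < to`).
#' @export
common_network <- function(average_models) {
  stopifnot(length(average_models) >= 1L)
  nodes <- average_models[[1]]$nodes
  keys <- lapply(average_models, function(g) edge_keys(skeleton_edges(g)))
  shared <- Reduce(intersect, keys)
  M <- length(average_models)
  if (length(shared)) {
    pair <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
    fwd <- numeric(length(shared))
    for (g in average_models) {
      a <- g$amat
      for (e in seq_along(shared)) {
        x <- pair[e, 1]; y <- pair[e, 2]
        fwd[e] <- fwd[e] +
          if (a[x, y] == 1L && a[y, x] == 0L) 1 else
            if (a[x, y] == 1L && a[y, x] == 1L) 0.5 else 0
      }
    }
    edges <- data.frame(from = pair[, 1], to = pair[, 2],
                        freq_forward = fwd / M, n_models = M)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        freq_forward = numeric(0), n_models = integer(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "g4_consensus")
}

#' @export
print.g4_consensus <- function(x, ...) {
  cat("Consensus network:", nrow(x$edges), "shared edge(s) over",
      length(x$nodes), "nodes\n")
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Resolve edge directions of a consensus network
#'
#' Keeps, for each shared edge, the direction with the higher empirical
#' frequency; an exact 0.5/0.5 tie stays undirected.  Any edge that would
#' point into a node in `protected` (for TF-specific networks, the G4
#' stability node: an effect on a sequence-intrinsic property would be
#' causally incoherent) is conservatively made undirected instead.
#'
#' @param net a `g4_consensus` from [common_network()].
#' @param protected character vector of nodes that may not receive a
#'   directed edge (default none; use `"Stability"` in TF-network mode).
#' @return a `g4_pdag`.
#' @export
resolve_directions <- function(net, protected = character(0)) {
  stopifnot(inherits(net, "g4_consensus"))
  p <- length(net$nodes)
  amat <- matrix(0L, p, p, dimnames = list(net$nodes, net$nodes))
  for (e in seq_len(nrow(net$edges))) {
    x <- net$edges$from[e]; y <- net$edges$to[e]
    f <- net$edges$freq_forward[e]
    if (f > 0.5) { from <- x; to <- y }
    else if (f < 0.5) { from <- y; to <- x }
    else { from <- NA; to <- NA }
    if (is.na(from) || to %in% protected) {
      amat[x, y] <- amat[y, x] <- 1L
    } else {
      amat[from, to] <- 1L
    }
  }
  pdag_from_amat_checked(amat)
}
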