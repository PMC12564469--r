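# Directed-graph helpers shared by the simulator, the d-separation oracle and
# the DAG -> CPDAG converter.  DAGs are g4_pdag objects whose undirected edge
# set is empty.

#' Build a DAG from an edge list
#'
#' @param nodes character vector of node names.
#' @param edges two-column character matrix/data.frame of from -> to pairs
#'   (may be empty or `NULL`).
#' @return a `g4_pdag` with only directed edges.
#' @export
dag <- function(nodes, edges = NULL) {
  g <- pdag(nodes, directed = edges)
  if (nrow(undirected_edges(g)) > 0L)
    stop("a DAG cannot contain undirected (reciprocal) edges")
  g
}

is_dag <- function(g) {
  inherits(g, "g4_pdag") && all(!(g$amat == 1L & t(g$amat) == 1L))
}

# acyclicity of the directed part (undirected edges ignored)
is_acyclic_directed_part <- function(g) {
  a <- g$amat
  d <- a == 1L & t(a) == 0L
  n <- nrow(d)
  indeg <- colSums(d)
  active <- rep(TRUE, n)
  repeat {
    src <- which(active & indeg == 0L)
    if (length(src) == 0L) break
    for (s in src) {
      indeg <- indeg - d[s, ]
      active[s] <- FALSE
    }
  }
  !any(active)
}

#' Topological order of a DAG
#'
#' @param g a `g4_pdag` with no undirected edges.
#' @return node names ordered so that every edge points forward.  Kahn's
#'   algorithm with first-index tie-breaking, so the order is deterministic.
#' @export
topological_sort <- function(g) {
  if (!is_dag(g)) stop("topological_sort() needs a DAG")
  a <- g$amat
  n <- nrow(a)
  indeg <- colSums(a)
  out <- integer(0)
  active <- rep(TRUE, n)
  while (length(out) < n) {
    s <- which(active & indeg == 0L)[1]
    if (is.na(s)) stop("graph is cyclic")
    out <- c(out, s)
    active[s] <- FALSE
    indeg <- indeg - a[s, ]
  }
  g$nodes[out]
}

parents_of <- function(g, v) g$nodes[g$amat[, v] == 1L & g$amat[v, ] == 0L]
children_of <- function(g, v) g$nodes[g$amat[v, ] == 1L & g$amat[, v] == 0L]

# all nodes with a directed path into any member of `vs`, plus `vs` itself
ancestors_of <- function(g, vs) {
  a <- g$amat == 1L & t(g$amat) == 0L
  seen <- g$nodes %in% vs
  repeat {
    reach <- a[, seen, drop = FALSE]
    new <- rowSums(reach) > 0L & !seen
    if (!any(new)) break
    seen <- seen | new
  }
  g$nodes[seen]
}

descendants_of <- function(g, vs) {
  a <- g$amat == 1L & t(g$amat) == 0L
  seen <- g$nodes %in% vs
  repeat {
    reach <- t(a)[, seen, drop = FALSE]
    new <- rowSums(reach) > 0L & !seen
    if (!any(new)) break
    seen <- seen | new
  }
  g$nodes[seen]
}

# TRUE iff a directed path from x to y exists in the directed part of g
has_directed_path <- function(g, x, y) y %in% descendants_of(g, x)

#' Random DAG generator
#'
#' Draws a labelled DAG uniformly over topological orderings: a random node
#' permutation, then each forward pair becomes an edge independently with
#' probability `p_edge`.  Used for benchmarking and property tests.
#'
#' @param nodes node names.
#' @param p_edge edge probability in (0, 1).
#' @return a DAG as a `g4_pdag`.
#' @export
random_dag <- function(nodes, p_edge = 0.4) {
  n <- length(nodes)
  ord <- sample(nodes)
  edges <- NULL
  if (n >= 2) {
    pairs <- t(utils::combn(ord, 2))   # respects the sampled order
    keep <- stats::runif(nrow(pairs)) < p_edge
    edges <- pairs[keep, , drop = FALSE]
  }
  dag(nodes, edges)
}

#' Enumerate every labelled DAG on a node set
#'
#' Walks all orientations of all subsets of node pairs and keeps the acyclic
#' ones.  Feasible up to 4 nodes (543 DAGs); used as an exhaustive oracle for
#' structure-learning tests.
#'
#' @param nodes node names (at most 4 for a practical run time).
#' @return list of `g4_pdag` DAGs.
#' @export
enumerate_dags <- function(nodes) {
  n <- length(nodes)
  if (n > 4) stop("exhaustive DAG enumeration is limited to 4 nodes")
  pairs <- if (n >= 2) t(utils::combn(nodes, 2)) else matrix(character(0), 0, 2)
  m <- nrow(pairs)
  out <- list()
  # each pair is absent (0), forward (1) or backward (2)
  states <- rep(0L, m)
  repeat {
    e <- NULL
    for (k in seq_len(m)) {
      if (states[k] == 1L) e <- rbind(e, pairs[k, , drop = FALSE])
      if (states[k] == 2L) e <- rbind(e, pairs[k, 2:1, drop = FALSE])
    }
    g <- tryCatch(dag(nodes, e), error = function(cnd) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
    # increment base-3 counter
    k <- 1L
    while (k <= m) {
      states[k] <- states[k] + 1L
      if (states[k] <= 2L) break
      states[k] <- 0L
      k <- k + 1L
    }
    if (k > m) break
  }
  out
}
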