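#' d-separation in a DAG
#'
#' Decides whether the node sets `A` and `B` are d-separated by `S`: every
#' path between them must be blocked, where a path is blocked by `S` if it
#' contains a chain (-> Z ->) or fork (<- Z ->) with Z in `S`, or a collider
#' (-> Z <-) with neither Z nor any descendant of Z in `S`.  Implemented by
#' the linear-time reachability ("Bayes-ball") traversal over (node,
#' direction-of-travel) states rather than path enumeration.
#'
#' @param g a DAG (`g4_pdag` with no undirected edges).
#' @param A,B,S disjoint character vectors of node names (`S` may be empty).
#' @return `TRUE` iff `A` and `B` are d-separated given `S`.
#' @examples
#' g <- dag(c("X", "Z", "Y"), rbind(c("X", "Z"), c("Y", "Z")))
#' d_separated(g, "X", "Y", character(0))  # collider unconditioned: TRUE
#' d_separated(g, "X", "Y", "Z")           # conditioning opens it: FALSE
#' @export
d_separated <- function(g, A, B, S = character(0)) {
  if (!is_dag(g)) stop("d_separated() requires an acyclic directed graph")
  nodes <- g$nodes
  A <- as.character(A); B <- as.character(B); S <- as.character(S)
  if (!all(c(A, B, S) %in% nodes)) stop("unknown node name")
  if (length(intersect(A, B)) || length(intersect(A, S)) ||
      length(intersect(B, S)))
    stop("A, B and S must be disjoint")
  if (length(A) == 0L || length(B) == 0L) return(TRUE)

  amat <- g$amat
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  in_S <- nodes %in% S
  in_B <- nodes %in% B
  anc_S <- nodes %in% ancestors_of(g, S)   # includes S itself

  # visited[v, 1]: reached travelling "up" (from a child); [v, 2]: "down"
  visited <- matrix(FALSE, n, 2)
  queue_v <- idx[A]
  queue_d <- rep(1L, length(queue_v))
  while (length(queue_v)) {
    v <- queue_v[1]; d <- queue_d[1]
    queue_v <- queue_v[-1]; queue_d <- queue_d[-1]
    if (visited[v, d]) next
    visited[v, d] <- TRUE
    if (!in_S[v] && in_B[v]) return(FALSE)
    pa <- idx[parents_of(g, nodes[v])]
    ch <- idx[children_of(g, nodes[v])]
    if (d == 1L) {            # arrived from a child (or a source node)
      if (!in_S[v]) {
        queue_v <- c(queue_v, pa, ch)
        queue_d <- c(queue_d, rep(1L, length(pa)), rep(2L, length(ch)))
      }
    } else {                  # arrived from a parent
      if (!in_S[v]) {
        queue_v <- c(queue_v, ch)
        queue_d <- c(queue_d, rep(2L, length(ch)))
      }
      if (anc_S[v]) {         # collider opened by S or a descendant in S
        queue_v <- c(queue_v, pa)
        queue_d <- c(queue_d, rep(1L, length(pa)))
      }
    }
  }
  TRUE
}

#' Oracle conditional-independence test from a known DAG
#'
#' Wraps [d_separated()] as a drop-in `ci_test` for [pc_stable()]: returns
#' p = 1 when the pair is d-separated given S in `g`, else p = 0.  Used to
#' check structure learning against ground truth without sampling noise.
#'
#' @param g the true DAG.
#' @return a function `(data, x, y, S) -> p-value` (the `data` argument is
#'   ignored).
#' @export
dsep_ci_test <- function(g) {
  force(g)
  function(data, x, y, S = character(0)) {
    if (d_separated(g, x, y, S)) 1 else 0
  }
}
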