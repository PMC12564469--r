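#' Completed partially directed graph of a DAG's equivalence class
#'
#' Converts a DAG into its CPDAG: edges whose direction is shared by every
#' DAG in the Markov equivalence class (compelled edges) stay directed, the
#' rest become undirected.  Uses Chickering's order-edges / label-edges
#' characterization, which works edge-by-edge from a topological order and
#' does not rely on the Meek orientation rules, so it can serve as an
#' independent oracle for [pc_stable()].
#'
#' @param g a DAG (`g4_pdag` with no undirected edges).
#' @return a `g4_pdag` (the CPDAG).
#' @examples
#' dag_to_cpdag(dag(c("X", "Y"), rbind(c("X", "Y"))))   # single edge: undirected
#' @export
dag_to_cpdag <- function(g) {
  if (!is_dag(g)) stop("dag_to_cpdag() requires a DAG")
  nodes <- g$nodes
  topo <- topological_sort(g)
  rank <- stats::setNames(seq_along(topo), topo)

  de <- directed_edges(g)
  if (nrow(de) == 0L) return(g)
  # order: destination ascending in topological rank, source descending
  ord <- order(rank[de[, 2]], -rank[de[, 1]])
  de <- de[ord, , drop = FALSE]
  m <- nrow(de)
  label <- rep(NA_character_, m)       # NA = unknown
  ekey <- paste(de[, 1], de[, 2])
  eidx <- function(from, to) match(paste(from, to), ekey)

  while (anyNA(label)) {
    e <- which(is.na(label))[1]
    x <- de[e, 1]; y <- de[e, 2]
    done <- FALSE
    for (w in parents_of(g, x)) {
      if (!identical(label[eidx(w, x)], "compelled")) next
      if (!(w %in% parents_of(g, y))) {
        into_y <- which(de[, 2] == y & is.na(label))
        label[into_y] <- "compelled"
        done <- TRUE
        break
      } else {
        label[eidx(w, y)] <- "compelled"
      }
    }
    if (!done) {
      pa_y <- parents_of(g, y)
      pa_x <- parents_of(g, x)
      if (any(pa_y != x & !(pa_y %in% pa_x))) {
        into_y <- which(de[, 2] == y & is.na(label))
        label[into_y] <- "compelled"
      } else {
        into_y <- which(de[, 2] == y & is.na(label))
        label[into_y] <- "reversible"
      }
    }
  }

  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (e in seq_len(m)) {
    amat[de[e, 1], de[e, 2]] <- 1L
    if (label[e] == "reversible") amat[de[e, 2], de[e, 1]] <- 1L
  }
  pdag_from_amat(amat)
}
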