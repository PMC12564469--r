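#' Partially directed acyclic graphs
#'
#' A `g4_pdag` stores the output of constraint-based structure learning and of
#' the consensus layers built on top of it: a node set together with directed
#' and undirected edges.  Internally the graph is an integer adjacency matrix
#' `amat` with `amat[i, j] == 1 && amat[j, i] == 0` meaning the directed edge
#' i -> j, and `amat[i, j] == 1 && amat[j, i] == 1` meaning the undirected
#' edge i - j.
#'
#' @param nodes character vector of variable names (unique, non-empty).
#' @param directed two-column character matrix (or data.frame) of directed
#'   edges, one row per from -> to pair.  May be `NULL`.
#' @param undirected two-column character matrix of undirected edges.  May be
#'   `NULL`.
#'
#' @return an object of class `g4_pdag`.
#' @examples
#' g <- pdag(c("X", "Z", "Y"), directed = rbind(c("X", "Z"), c("Y", "Z")))
#' directed_edges(g)
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L || anyDuplicated(nodes))
    stop("'nodes' must be a non-empty set of unique names")
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  norm_edges <- function(e) {
    if (is.null(e) || NROW(e) == 0L) return(NULL)
    e <- as.matrix(e)
    storage.mode(e) <- "character"
    if (ncol(e) != 2L) stop("edge input must have two columns")
    if (!all(e %in% nodes)) stop("edge endpoints must be listed in 'nodes'")
    e
  }
  d <- norm_edges(directed)
  if (!is.null(d)) amat[d] <- 1L
  u <- norm_edges(undirected)
  if (!is.null(u)) {
    amat[u] <- 1L
    amat[u[, 2:1, drop = FALSE]] <- 1L
  }
  pdag_from_amat(amat)
}

#' @param amat square 0/1 integer matrix with dimnames; see [pdag()] for the
#'   encoding.
#' @rdname pdag
#' @export
pdag_from_amat <- function(amat) {
  stopifnot(is.matrix(amat), nrow(amat) == ncol(amat),
            !is.null(rownames(amat)))
  storage.mode(amat) <- "integer"
  if (any(amat != 0L & amat != 1L)) stop("'amat' entries must be 0/1")
  if (any(diag(amat) != 0L)) stop("self-loops are not allowed")
  g <- structure(list(nodes = rownames(amat), amat = amat),
                 class = "g4_pdag")
  if (!is_acyclic_directed_part(g))
    stop("directed subgraph of a PDAG must be acyclic")
  g
}

#' @export
print.g4_pdag <- function(x, ...) {
  d <- directed_edges(x)
  u <- undirected_edges(x)
  cat("Partially directed graph over", length(x$nodes), "nodes\n")
  cat("  nodes:", paste(x$nodes, collapse = ", "), "\n")
  cat("  directed edges:  ",
      if (nrow(d)) paste(d[, 1], "->", d[, 2], collapse = ", ") else "none",
      "\n")
  cat("  undirected edges:",
      if (nrow(u)) paste(u[, 1], "--", u[, 2], collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Edge accessors for PDAGs
#'
#' `directed_edges()` and `undirected_edges()` return two-column character
#' matrices (from/to; undirected rows are in lexicographic order).
#' `skeleton_edges()` returns every adjacency, directed or not, as an
#' unordered pair.  `n_edges()` counts adjacencies.
#'
#' @param g a `g4_pdag`.
#' @return a two-column character matrix (or an integer for `n_edges`).
#' @export
directed_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  m <- cbind(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname directed_edges
#' @export
undirected_edges <- function(g) {
  a <- g$amat
  idx <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  m <- cbind(from = g$nodes[pmin(idx[, 1], idx[, 2])],
             to   = g$nodes[pmax(idx[, 1], idx[, 2])])
  # node order in the matrix may not be lexicographic; canonicalise
  swap <- m[, 1] > m[, 2]
  m[swap, ] <- m[swap, 2:1]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname directed_edges
#' @export
skeleton_edges <- function(g) {
  a <- (g$amat + t(g$amat)) > 0L
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  m <- cbind(from = g$nodes[idx[, 1]], to = g$nodes[idx[, 2]])
  swap <- m[, 1] > m[, 2]
  m[swap, ] <- m[swap, 2:1]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' @rdname directed_edges
#' @export
n_edges <- function(g) nrow(skeleton_edges(g))

# keys of unordered pairs, used throughout the consensus layer
edge_keys <- function(e) {
  if (NROW(e) == 0L) return(character(0))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "\r")
}

#' Structural Hamming distance between two graphs
#'
#' With `directed = FALSE` (the default) the distance counts adjacencies
#' present in exactly one of the two skeletons.  With `directed = TRUE` an
#' adjacency present in both but with a different orientation status also
#' counts one.
#'
#' @param g1,g2 `g4_pdag` objects over the same node set.
#' @param directed compare orientations as well as adjacencies?
#' @return a non-negative integer.
#' @export
shd <- function(g1, g2, directed = FALSE) {
  stopifnot(setequal(g1$nodes, g2$nodes))
  a1 <- g1$amat[g1$nodes, g1$nodes]
  a2 <- g2$amat[g1$nodes, g1$nodes]
  s1 <- (a1 + t(a1)) > 0L
  s2 <- (a2 + t(a2)) > 0L
  mism <- (s1 != s2)
  if (directed) {
    both <- s1 & s2
    mism <- mism | (both & (a1 != a2 | t(a1) != t(a2)))
  }
  sum(mism[upper.tri(mism)])
}

#' Serialize a PDAG
#'
#' `pdag_adjacency()` returns the integer adjacency matrix in the reporting
#' convention 0 = no edge, 1 = directed row -> column, 2 = undirected;
#' `write_pdag()` writes it as TSV alongside an edge-list TSV with a
#' `type` column (`directed`/`undirected`).
#'
#' @param g a `g4_pdag`.
#' @param file base path; `write_pdag` writes `<file>.adjacency.tsv` and
#'   `<file>.edges.tsv`.
#' @return `pdag_adjacency`: an integer matrix; `write_pdag`: the two paths,
#'   invisibly.
#' @export
pdag_adjacency <- function(g) {
  a <- g$amat
  out <- matrix(0L, nrow(a), ncol(a), dimnames = dimnames(a))
  out[a == 1L & t(a) == 0L] <- 1L
  out[a == 1L & t(a) == 1L] <- 2L
  out
}

#' @rdname pdag_adjacency
#' @export
write_pdag <- function(g, file) {
  adj <- pdag_adjacency(g)
  p1 <- paste0(file, ".adjacency.tsv")
  df <- data.frame(node = rownames(adj), adj, check.names = FALSE)
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  d <- directed_edges(g)
  u <- undirected_edges(g)
  el <- rbind(
    if (nrow(d)) data.frame(from = d[, 1], to = d[, 2], type = "directed"),
    if (nrow(u)) data.frame(from = u[, 1], to = u[, 2], type = "undirected")
  )
  if (is.null(el)) el <- data.frame(from = character(0), to = character(0),
                                    type = character(0))
  p2 <- paste0(file, ".edges.tsv")
  utils::write.table(el, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
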