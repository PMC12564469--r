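#' PC-stable structure learning
#'
#' Learns a partially directed graph (CPDAG-like) over discrete variables by
#' the order-independent variant of the PC algorithm: the skeleton search
#' proceeds level-wise with the adjacency sets frozen at the start of each
#' level, so the result does not depend on the order of the columns.  Edge
#' removal is decided by a conditional-independence test (by default the
#' Monte-Carlo permutation chi-squared test, see [permutation_ci_test()]):
#' an edge x - y is removed as soon as some subset S of a frozen neighbour
#' set satisfies p(x, y | S) > alpha, and S is recorded as the separating
#' set.  v-structures x -> z <- y are then oriented wherever z lies outside
#' the recorded separating set of a non-adjacent pair, and the Meek rules
#' R1-R4 are applied to a fixed point.  Orientation conflicts (two
#' v-structures disagreeing about one edge) leave the affected edge
#' undirected, with a message.
#'
#' @param data data.frame of discrete columns; a column named `stratum` is
#'   ignored (it labels the sampling stratum, it is not a variable).
#' @param ci_test function `(data, x, y, S) -> p-value`; defaults to the
#'   permutation chi-squared test under `config`.  [dsep_ci_test()] supplies
#'   an exact oracle for simulations.
#' @param config a [ci_test_config()]; `config$seed`, when set, seeds the RNG
#'   once before the run so identical configurations reproduce identical
#'   networks (tests are executed in deterministic (x, y, S, level) order).
#' @param max_cond maximum conditioning-set size; default `NULL` means
#'   unrestricted (|V| - 2).
#' @param nodes variables to use; defaults to every column except `stratum`.
#' @return a list with `graph` (a `g4_pdag`) and `sepsets` (a named list:
#'   key `"x|y"` with x < y, value the separating character vector).
#' @examples
#' g <- dag(c("X", "Z", "Y"), rbind(c("X", "Z"), c("Y", "Z")))
#' fit <- pc_stable(NULL, ci_test = dsep_ci_test(g), nodes = g$nodes)
#' directed_edges(fit$graph)   # the collider is recovered
#' @export
pc_stable <- function(data, ci_test = NULL, config = ci_test_config(),
                      max_cond = NULL, nodes = NULL) {
  if (is.null(nodes)) {
    if (is.null(data)) stop("supply 'nodes' when 'data' is NULL")
    nodes <- setdiff(names(data), "stratum")
  }
  p <- length(nodes)
  if (p < 3L) stop("structure learning needs at least 3 variables")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(ci_test)) {
    # precompute level codes once; every test then runs on integer codes
    prep <- .ci_prep(data, nodes)
    B <- config$B
    ci_test <- function(data, x, y, S) {
      as.numeric(.perm_ci_fast(prep, x, y, S, B))
    }
  }
  if (is.null(max_cond)) max_cond <- p - 2L
  alpha <- config$alpha

  adj <- matrix(TRUE, p, p, dimnames = list(nodes, nodes))
  diag(adj) <- FALSE
  sepsets <- list()

  ell <- 0L
  repeat {
    frozen <- adj                      # PC-stable: freeze neighbour sets
    any_testable <- FALSE
    for (i in seq_len(p)) {
      x <- nodes[i]
      for (j in seq_len(p)) {
        if (i == j || !adj[i, j]) next
        y <- nodes[j]
        nb <- nodes[frozen[i, ]]
        nb <- setdiff(nb, y)
        if (length(nb) < ell) next
        any_testable <- TRUE
        subsets <- if (ell == 0L) list(character(0)) else
          utils::combn(nb, ell, simplify = FALSE)
        for (S in subsets) {
          pval <- ci_test(data, x, y, S)
          if (pval > alpha) {
            adj[i, j] <- adj[j, i] <- FALSE
            key <- paste(sort(c(x, y)), collapse = "|")
            sepsets[[key]] <- S
            break
          }
        }
      }
    }
    ell <- ell + 1L
    if (!any_testable || ell > max_cond) break
  }

  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  amat[adj] <- 1L                      # all edges undirected for now

  # orient v-structures x -> z <- y for non-adjacent x, y with common
  # neighbour z not in sepset(x, y); collect votes, conflicts -> undirected
  into <- matrix(FALSE, p, p, dimnames = list(nodes, nodes)) # [a,b]: a -> b
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      if (adj[i, j]) next
      x <- nodes[i]; y <- nodes[j]
      key <- paste(sort(c(x, y)), collapse = "|")
      S <- sepsets[[key]]
      if (is.null(S)) next             # never separated (e.g. level cap hit)
      zs <- nodes[adj[i, ] & adj[j, ]]
      for (z in setdiff(zs, S)) {
        into[x, z] <- TRUE
        into[y, z] <- TRUE
      }
    }
  }
  conflict <- into & t(into)
  if (any(conflict))
    message("conflicting v-structure orientations on ",
            sum(conflict) / 2, " edge(s); left undirected")
  orient <- into & !conflict
  amat[t(orient)] <- 0L                # a -> b: drop the b -> a half

  g <- pdag_from_amat_checked(amat)
  g <- apply_meek_rules(g)
  list(graph = g, sepsets = sepsets)
}

# v-structure orientation cannot create directed cycles from a skeleton, but
# guard anyway: if it ever would, fall back to leaving the offenders
# undirected rather than erroring mid-run.
pdag_from_amat_checked <- function(amat) {
  tryCatch(pdag_from_amat(amat), error = function(cnd) {
    sym <- amat + t(amat) > 0L
    amat[sym] <- 1L
    pdag_from_amat(amat)
  })
}

#' Meek orientation rules
#'
#' Applies Meek's rules R1-R4 to a partially directed graph until no rule
#' fires, orienting undirected edges whose direction is compelled by the
#' already-directed ones.  An orientation that would create a directed cycle
#' is skipped (with a message); this cannot occur on conflict-free inputs.
#'
#' R1: z -> x, x - y, z and y non-adjacent  =>  x -> y.
#' R2: x -> z -> y, x - y                   =>  x -> y.
#' R3: x - z, x - w, z -> y, w -> y, x - y, z and w non-adjacent  =>  x -> y.
#' R4: x - w, w -> z, z -> y, x - y, x and z adjacent, w and y
#'     non-adjacent  =>  x -> y.
#'
#' @param g a `g4_pdag`.
#' @return the closed `g4_pdag`.
#' @export
apply_meek_rules <- function(g) {
  nodes <- g$nodes
  a <- g$amat
  p <- length(nodes)
  und <- function() which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  dir_ok <- function(x, y) {  # directing x -> y keeps the directed part acyclic
    !has_directed_path(pdag_from_amat(a), nodes[y], nodes[x])
  }
  set_dir <- function(x, y) a[y, x] <<- 0L
  repeat {
    fired <- FALSE
    ue <- und()
    if (nrow(ue)) ue <- rbind(ue, ue[, 2:1, drop = FALSE])  # both orientations
    for (r in seq_len(nrow(ue))) {
      x <- ue[r, 1]; y <- ue[r, 2]
      if (!(a[x, y] == 1L && a[y, x] == 1L)) next  # already oriented this pass
      adj_x <- a[x, ] == 1L | a[, x] == 1L
      adj_y <- a[y, ] == 1L | a[, y] == 1L
      dpa_x <- a[, x] == 1L & a[x, ] == 0L   # z -> x
      dch_x <- a[x, ] == 1L & a[, x] == 0L   # x -> z
      fire <- FALSE
      # R1: exists z -> x with z, y non-adjacent
      if (any(dpa_x & !adj_y & seq_len(p) != y)) fire <- TRUE
      # R2: exists z with x -> z -> y
      if (!fire && any(dch_x & (a[, y] == 1L & a[y, ] == 0L))) fire <- TRUE
      if (!fire) {
        # R3: z, w both undirected-adjacent to x, both -> y, z/w non-adjacent
        cand <- which(a[x, ] == 1L & a[, x] == 1L &
                        a[, y] == 1L & a[y, ] == 0L)
        if (length(cand) >= 2L) {
          for (ii in seq_along(cand)) {
            for (jj in seq_along(cand)) {
              if (ii >= jj) next
              z <- cand[ii]; w <- cand[jj]
              if (a[z, w] == 0L && a[w, z] == 0L) { fire <- TRUE; break }
            }
            if (fire) break
          }
        }
      }
      if (!fire) {
        # R4: w with x - w, w -> z, z -> y, x adjacent z, w/y non-adjacent
        for (w in which(a[x, ] == 1L & a[, x] == 1L)) {
          zs <- which(a[w, ] == 1L & a[, w] == 0L)       # w -> z
          for (z in zs) {
            if (a[z, y] == 1L && a[y, z] == 0L &&        # z -> y
                (a[x, z] == 1L || a[z, x] == 1L) &&      # x adjacent z
                a[w, y] == 0L && a[y, w] == 0L && w != y) {
              fire <- TRUE; break
            }
          }
          if (fire) break
        }
      }
      if (fire) {
        if (dir_ok(x, y)) {
          set_dir(x, y)
          fired <- TRUE
        } else {
          message("Meek orientation skipped: ", nodes[x], " -> ", nodes[y],
                  " would create a directed cycle")
        }
      }
    }
    if (!fired) break
  }
  pdag_from_amat(a)
}
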