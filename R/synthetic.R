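#' Ground-truth specification for the discrete simulator
#'
#' A `g4_gt_spec` couples a DAG over named variables with one conditional
#' probability table (CPT) per node and a set of sampling strata (standing in
#' for cell lines).  [simulate_observations()] draws discrete observations
#' from it by ancestral sampling, giving the structure-learning stack a
#' recoverable truth.
#'
#' Each element of `cpts` is a list with fields `parents` (character, must
#' equal the node's parents in `edges`), `levels` (the node's category
#' labels) and `prob`, a matrix with one row per parent configuration and one
#' column per level.  Parent configurations are enumerated in
#' [expand.grid()] order over the parents' levels (first parent varying
#' fastest); a root node has a single-row `prob`.  Rows must sum to 1 within
#' 1e-9.
#'
#' @param nodes character vector of variable names.
#' @param edges two-column matrix of directed edges; must be acyclic.
#' @param cpts named list of CPTs, one per node (see Details).
#' @param strata character vector of stratum names.
#' @param root_overrides optional named list `stratum -> node -> probability
#'   row` replacing a *root* node's CPT in that stratum only (models
#'   cell-line-specific marginals).
#' @return an object of class `g4_gt_spec`.
#' @seealso [g4_ground_truth()] for the shipped default specification.
#' @export
ground_truth_spec <- function(nodes, edges, cpts, strata = "S1",
                              root_overrides = NULL) {
  g <- dag(nodes, edges)          # errors on cycles
  stopifnot(is.list(cpts), setequal(names(cpts), nodes),
            is.character(strata), length(strata) >= 1L)
  for (v in nodes) {
    cpt <- cpts[[v]]
    pa <- parents_of(g, v)
    if (!setequal(cpt$parents, pa))
      stop("CPT of '", v, "' conditions on {",
           paste(cpt$parents, collapse = ", "),
           "} but its parents are {", paste(pa, collapse = ", "), "}")
    nconf <- prod(vapply(cpt$parents, function(p) length(cpts[[p]]$levels),
                         integer(1)))
    if (length(cpt$parents) == 0L) nconf <- 1L
    if (!is.matrix(cpt$prob) || nrow(cpt$prob) != nconf ||
        ncol(cpt$prob) != length(cpt$levels))
      stop("CPT of '", v, "' has the wrong shape")
    if (any(abs(rowSums(cpt$prob) - 1) > 1e-9))
      stop("CPT rows of '", v, "' must sum to 1")
    if (any(cpt$prob < 0)) stop("CPT of '", v, "' has negative entries")
  }
  if (!is.null(root_overrides)) {
    stopifnot(all(names(root_overrides) %in% strata))
    for (st in names(root_overrides)) {
      for (v in names(root_overrides[[st]])) {
        if (length(parents_of(g, v)) > 0L)
          stop("per-stratum override allowed for root nodes only ('", v, "')")
        pr <- root_overrides[[st]][[v]]
        if (length(pr) != length(cpts[[v]]$levels) || abs(sum(pr) - 1) > 1e-9)
          stop("override for '", v, "' in '", st, "' is not a distribution")
      }
    }
  }
  structure(list(nodes = nodes, graph = g, cpts = cpts, strata = strata,
                 root_overrides = root_overrides),
            class = "g4_gt_spec")
}

#' @export
print.g4_gt_spec <- function(x, ...) {
  cat("Ground-truth DAG spec:", length(x$nodes), "nodes,",
      nrow(directed_edges(x$graph)), "edges,",
      length(x$strata), "strata\n")
  print(x$graph)
  invisible(x)
}

#' Eight-group chromatin-state vocabulary
#'
#' The 18 ChromHMM states collapsed into 8 functional groups (TSS, Tx, EnhG,
#' Enh, HetZNF, Biv, ReprPC, Quies), the default cardinality of the simulated
#' `ChromState` variable: a full 18-level CPT would leave most parent
#' configurations nearly unobserved at realistic sample sizes.
#'
#' @return named character vector mapping each of the 18 states to its group.
#' @export
chromhmm18_groups <- function() {
  c(TssA = "TSS", TssFlnk = "TSS", TssFlnkU = "TSS", TssFlnkD = "TSS",
    Tx = "Tx", TxWk = "Tx",
    EnhG1 = "EnhG", EnhG2 = "EnhG",
    EnhA1 = "Enh", EnhA2 = "Enh", EnhWk = "Enh",
    "ZNF/Rpts" = "HetZNF", Het = "HetZNF",
    TssBiv = "Biv", EnhBiv = "Biv",
    ReprPC = "ReprPC", ReprPCWk = "ReprPC",
    Quies = "Quies")
}

#' The 18 ChromHMM state labels
#' @return character vector of the 18-state vocabulary.
#' @export
chromhmm18_states <- function() names(chromhmm18_groups())

# logistic CPT for a binary child: P(High) = plogis(effect * w), where w is
# the centred, scaled count of "High" binary parents plus an optional
# chromatin-state score
.binary_levels <- c("Low", "High")

#' Shipped ground-truth network for G4 signal simulation
#'
#' The default six-node topology mirrors the causal structure reported for
#' eG4 regions: `Stability -> {ChromState, TFs, eG4s}`,
#' `phyloP -> {ChromState, TFs}`, `ATACSig -> {ChromState, TFs}` and
#' `ChromState -> TFs` (8 edges).  `Stability`, `phyloP` and `ATACSig` are
#' Bernoulli(`root_p`) roots; each binary child is logistic in the centred
#' fraction of "High" parents with slope `effect`; `ChromState` is a
#' categorical child over `state_groups` whose log-probabilities are linear
#' in an ordered state score times the same parent summary.  The default
#' `effect` makes every edge comfortably detectable at the study's sample
#' size (about 7000 regions per cell line, three cell lines).
#'
#' @param effect logistic slope shared by all child CPTs (default 1.5).
#' @param state_groups labels of the chromatin-state variable (default the 8
#'   collapsed groups from [chromhmm18_groups()]).
#' @param strata stratum (cell line) names.
#' @param root_p probability of "High" for the three root variables.
#' @param root_overrides see [ground_truth_spec()].
#' @return a `g4_gt_spec`.
#' @examples
#' spec <- g4_ground_truth()
#' directed_edges(spec$graph)
#' @export
g4_ground_truth <- function(effect = 1.5,
                            state_groups = unique(chromhmm18_groups()),
                            strata = c("K562", "HepG2", "HEK293T"),
                            root_p = 0.5,
                            root_overrides = NULL) {
  nodes <- c("Stability", "phyloP", "ATACSig", "ChromState", "eG4s", "TFs")
  edges <- rbind(
    c("Stability", "ChromState"), c("Stability", "TFs"),
    c("Stability", "eG4s"),
    c("phyloP", "ChromState"), c("phyloP", "TFs"),
    c("ATACSig", "ChromState"), c("ATACSig", "TFs"),
    c("ChromState", "TFs"))
  L <- length(state_groups)
  zstate <- if (L > 1) (2 * seq_len(L) - L - 1) / (L - 1) else 0  # in [-1, 1]

  root_cpt <- list(parents = character(0), levels = .binary_levels,
                   prob = matrix(c(1 - root_p, root_p), 1,
                                 dimnames = list(NULL, .binary_levels)))
  # eG4s | Stability: one binary parent, w in {-1, 1}
  eg4_prob <- t(vapply(c(-1, 1), function(w) {
    p <- stats::plogis(effect * w); c(1 - p, p)
  }, numeric(2)))
  colnames(eg4_prob) <- .binary_levels
  # ChromState | Stability, phyloP, ATACSig: softmax over state scores
  conf3 <- as.matrix(expand.grid(0:1, 0:1, 0:1))   # first parent fastest
  w3 <- (rowSums(conf3) - 1.5) / 1.5               # in [-1, 1]
  cs_prob <- t(vapply(w3, function(w) {
    e <- exp(effect * zstate * w); e / sum(e)
  }, numeric(L)))
  colnames(cs_prob) <- state_groups
  # TFs | Stability, phyloP, ATACSig, ChromState
  conf4 <- expand.grid(s = 0:1, p = 0:1, a = 0:1, cs = seq_len(L))
  wtf <- (rowSums(conf4[, 1:3]) - 1.5) / 1.5 + zstate[conf4$cs]
  tf_prob <- t(vapply(wtf, function(w) {
    p <- stats::plogis(effect * w); c(1 - p, p)
  }, numeric(2)))
  colnames(tf_prob) <- .binary_levels

  cpts <- list(
    Stability = root_cpt, phyloP = root_cpt, ATACSig = root_cpt,
    eG4s = list(parents = "Stability", levels = .binary_levels,
                prob = eg4_prob),
    ChromState = list(parents = c("Stability", "phyloP", "ATACSig"),
                      levels = state_groups, prob = cs_prob),
    TFs = list(parents = c("Stability", "phyloP", "ATACSig", "ChromState"),
               levels = .binary_levels, prob = tf_prob))
  ground_truth_spec(nodes, edges, cpts, strata = strata,
                    root_overrides = root_overrides)
}

# row index into a CPT's prob matrix given integer parent level codes
# (expand.grid order: first parent varying fastest)
.cpt_row_index <- function(spec, v, code_mat) {
  pa <- spec$cpts[[v]]$parents
  if (length(pa) == 0L) return(rep(1L, nrow(code_mat)))
  idx <- rep(1L, nrow(code_mat))
  mult <- 1L
  for (p in pa) {
    idx <- idx + (code_mat[, p] - 1L) * mult
    mult <- mult * length(spec$cpts[[p]]$levels)
  }
  idx
}

#' Simulate discrete observations from a ground-truth spec
#'
#' Ancestral (topological-order) sampling: each node is drawn from its CPT
#' row selected by the already-sampled parent values.  Rows are generated per
#' stratum; root-node CPTs may differ by stratum via the spec's
#' `root_overrides`.  The same `seed` always reproduces the same table.
#'
#' @param spec a [ground_truth_spec()].
#' @param n_per_stratum rows per stratum: a single count, or a vector with
#'   one count per stratum (recycled by name when named).
#' @param seed integer RNG seed (mandatory: the simulator is the reference
#'   input of stochastic acceptance checks).
#' @return data.frame of factor columns, one per node, plus a `stratum`
#'   column; `sum(n_per_stratum)` rows.
#' @examples
#' head(simulate_observations(g4_ground_truth(), 100, seed = 1))
#' @export
simulate_observations <- function(spec, n_per_stratum, seed) {
  stopifnot(inherits(spec, "g4_gt_spec"), all(n_per_stratum >= 0))
  set.seed(seed)
  ns <- n_per_stratum
  if (length(ns) == 1L) ns <- rep(ns, length(spec$strata))
  if (!is.null(names(ns))) ns <- ns[spec$strata]
  if (length(ns) != length(spec$strata) || anyNA(ns))
    stop("'n_per_stratum' must give one count per stratum")
  topo <- topological_sort(spec$graph)

  sample_stratum <- function(st, n) {
    codes <- matrix(1L, n, length(spec$nodes),
                    dimnames = list(NULL, spec$nodes))
    for (v in topo) {
      prob <- spec$cpts[[v]]$prob
      ov <- spec$root_overrides[[st]][[v]]
      if (!is.null(ov)) prob <- matrix(ov, 1)
      cum <- t(apply(prob, 1, cumsum))
      ri <- .cpt_row_index(spec, v, codes)
      u <- stats::runif(n)
      L <- ncol(prob)
      lev <- rep(1L, n)
      if (L > 1L)
        lev <- 1L + as.integer(
          rowSums(u > cum[ri, -L, drop = FALSE], dims = 1L))
      codes[, v] <- lev
    }
    codes
  }

  out <- vector("list", length(spec$strata))
  for (k in seq_along(spec$strata)) {
    codes <- sample_stratum(spec$strata[k], ns[k])
    cols <- lapply(spec$nodes, function(v)
      factor(spec$cpts[[v]]$levels[codes[, v]],
             levels = spec$cpts[[v]]$levels))
    df <- stats::setNames(as.data.frame(cols), spec$nodes)[seq_len(ns[k]), ,
                                                          drop = FALSE]
    df$stratum <- rep(spec$strata[k], ns[k])
    out[[k]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact joint distribution implied by a ground-truth spec
#'
#' Enumerates every configuration of the variables and multiplies the CPT
#' entries, optionally applying one stratum's root overrides.  Intended for
#' checking simulated frequencies against their exact targets.
#'
#' @param spec a `g4_gt_spec`.
#' @param stratum stratum whose root overrides to apply (default: none).
#' @return data.frame of one row per configuration with a `prob` column
#'   summing to 1.
#' @export
spec_joint_distribution <- function(spec, stratum = NULL) {
  grids <- lapply(spec$nodes, function(v) spec$cpts[[v]]$levels)
  names(grids) <- spec$nodes
  conf <- expand.grid(grids, stringsAsFactors = FALSE)
  codes <- vapply(spec$nodes, function(v)
    match(conf[[v]], spec$cpts[[v]]$levels), integer(nrow(conf)))
  prob <- rep(1, nrow(conf))
  for (v in spec$nodes) {
    pr <- spec$cpts[[v]]$prob
    if (!is.null(stratum)) {
      ov <- spec$root_overrides[[stratum]][[v]]
      if (!is.null(ov)) pr <- matrix(ov, 1)
    }
    ri <- .cpt_row_index(spec, v, codes)
    prob <- prob * pr[cbind(ri, codes[, v])]
  }
  conf$prob <- prob
  conf
}
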