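# Independent brute-force oracles used across the suite.  These deliberately
# re-derive every quantity from first principles (per-base scans, all-pairs
# loops, literal permutation, path enumeration) so they share no code with
# the implementation they check.

# ---- interval / mapping oracles (all 0-based half-open) ---------------------

o_mid <- function(s, e) (s + e) %/% 2L

o_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

oracle_filter <- function(regions, pg4s) {
  keep <- vapply(seq_len(nrow(regions)), function(i) {
    any(vapply(seq_len(nrow(pg4s)), function(j)
      regions$chrom[i] == pg4s$chrom[j] &&
        o_overlap(regions$start[i], regions$end[i],
                  pg4s$start[j], pg4s$end[j]), logical(1)))
  }, logical(1))
  regions[keep, , drop = FALSE]
}

# value of a track at a single base, NA if uncovered (first covering interval)
o_track_at <- function(track, chrom, pos, strand = NULL) {
  sel <- track$chrom == chrom & track$start <= pos & pos < track$end
  if (!is.null(strand)) sel <- sel & track$strand == strand
  v <- track$value[sel]
  if (length(v)) v[1] else NA_real_
}

oracle_window_max <- function(pg4s, track, window) {
  vapply(seq_len(nrow(pg4s)), function(i) {
    m <- o_mid(pg4s$start[i], pg4s$end[i])
    vals <- vapply((m - window %/% 2):(m + window %/% 2 - 1), function(p)
      o_track_at(track, pg4s$chrom[i], p, pg4s$strand[i]), numeric(1))
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }, numeric(1))
}

oracle_window_mean <- function(pg4s, track, window) {
  vapply(seq_len(nrow(pg4s)), function(i) {
    m <- o_mid(pg4s$start[i], pg4s$end[i])
    vals <- vapply((m - window %/% 2):(m + window %/% 2 - 1), function(p)
      o_track_at(track, pg4s$chrom[i], p), numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

oracle_assign <- function(regions, pg4s, values) {
  vapply(seq_len(nrow(regions)), function(i) {
    rm_ <- o_mid(regions$start[i], regions$end[i])
    cand <- which(vapply(seq_len(nrow(pg4s)), function(j)
      regions$chrom[i] == pg4s$chrom[j] &&
        o_overlap(regions$start[i], regions$end[i],
                  pg4s$start[j], pg4s$end[j]) && !is.na(values[j]),
      logical(1)))
    if (!length(cand)) return(NA_real_)
    d <- abs(o_mid(pg4s$start[cand], pg4s$end[cand]) - rm_)
    cand <- cand[order(d, pg4s$start[cand], pg4s$strand[cand] != "+")]
    values[cand[1]]
  }, numeric(1))
}

oracle_state <- function(regions, seg) {
  vapply(seq_len(nrow(regions)), function(i) {
    m <- o_mid(regions$start[i], regions$end[i])
    sel <- seg$chrom == regions$chrom[i] & seg$start <= m & m < seg$end
    if (any(sel)) seg$state[which(sel)[1]] else NA_character_
  }, character(1))
}

oracle_atac <- function(regions, frags, mean_depth) {
  vapply(seq_len(nrow(regions)), function(i) {
    cov <- 0
    for (p in regions$start[i]:(regions$end[i] - 1L))
      cov <- cov + sum(frags$chrom == regions$chrom[i] &
                         frags$start <= p & p < frags$end)
    (cov / (regions$end[i] - regions$start[i])) / mean_depth
  }, numeric(1))
}

oracle_tf <- function(regions, peaks) {
  tfs <- sort(unique(as.character(peaks$tf)))
  occ <- matrix(0L, nrow(regions), length(tfs), dimnames = list(NULL, tfs))
  for (i in seq_len(nrow(regions)))
    for (j in seq_len(nrow(peaks)))
      if (regions$chrom[i] == peaks$chrom[j] &&
          o_overlap(regions$start[i], regions$end[i],
                    peaks$start[j], peaks$end[j]))
        occ[i, peaks$tf[j]] <- occ[i, peaks$tf[j]] + 1L
  occ
}

# ---- d-separation oracle: explicit path enumeration -------------------------

# all simple paths between a and b over the skeleton, as node index vectors
o_all_paths <- function(amat, a, b) {
  n <- nrow(amat)
  adj <- (amat + t(amat)) > 0
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == b) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in which(adj[v, ])) if (!(w %in% path)) walk(c(path, w))
  }
  walk(a)
  paths
}

oracle_dsep <- function(g, x, y, S) {
  amat <- g$amat
  nodes <- g$nodes
  xi <- match(x, nodes); yi <- match(y, nodes)
  Si <- match(S, nodes)
  desc <- function(v) match(descendants_of(g, nodes[v]), nodes)
  for (path in o_all_paths(amat, xi, yi)) {
    blocked <- FALSE
    if (length(path) > 2L) {
      for (k in 2:(length(path) - 1L)) {
        prev <- path[k - 1L]; z <- path[k]; nxt <- path[k + 1L]
        collider <- amat[prev, z] == 1L && amat[nxt, z] == 1L
        if (collider) {
          if (!any(desc(z) %in% Si)) { blocked <- TRUE; break }
        } else {
          if (z %in% Si) { blocked <- TRUE; break }
        }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# ---- literal within-stratum permutation CI test -----------------------------

perm_ci_literal <- function(data, x, y, S, B) {
  t_obs <- chi2_statistic(data, x, y, S)
  key <- if (length(S)) interaction(data[S], drop = TRUE) else
    factor(rep(1, nrow(data)))
  exceed <- 0L
  d <- data
  for (b in seq_len(B)) {
    xs <- data[[x]]
    for (lev in levels(key)) {
      idx <- which(key == lev)
      xs[idx] <- xs[idx][sample.int(length(idx))]
    }
    d[[x]] <- xs
    if (chi2_statistic(d, x, y, S) >= t_obs - 1e-9) exceed <- exceed + 1L
  }
  (1 + exceed) / (B + 1)
}

# ---- fine-grid Riemann integral for the robustness AUC ----------------------

oracle_auc <- function(points) {
  o <- order(points$accuracy, points$coverage)
  x <- points$accuracy[o]; y <- points$coverage[o]
  grid <- seq(x[1], x[length(x)], length.out = 200001)
  yy <- stats::approx(x, y, xout = grid, ties = mean)$y
  mean(utils::head(yy, -1) + utils::tail(yy, -1)) / 2
}

# ---- misc -------------------------------------------------------------------

# tiny random genome fixture for oracle-equivalence property tests
rand_test_config <- function() {
  fixture_config(
    chrom_sizes = c(A = 1500L, B = 1000L),
    strata = "S1",
    n_regions = sample(2:5, 1), n_decoys = sample(0:2, 1),
    region_len = c(60L, 200L),
    pg4_per_region = c(1L, 2L), pg4_len = c(10L, 30L),
    n_bg_pg4 = sample(0:6, 1),
    mm_bin = 40L, mm_cover = 0.6,
    phylop_bin = 20L, phylop_cover = 0.7,
    seg_len = c(100L, 500L),
    n_atac_frags = sample(c(0L, 20L, 60L), 1),
    frag_len = c(40L, 150L),
    tf_names = c("SP1", "YY1"), peaks_per_tf = sample(c(0L, 5L, 10L), 1),
    peak_len = c(30L, 100L),
    n_tss = 6L)
}

# column-wise oracle recomputation of a fixture's region table
oracle_region_table <- function(fx, recruitment = "hits") {
  kept <- oracle_filter(fx$regions, fx$pg4s)
  st <- oracle_window_max(fx$pg4s, fx$mm_track, 150L)
  ph <- oracle_window_mean(fx$pg4s, fx$phylop_track, 50L)
  depth <- sum(fx$atac_fragments$end - fx$atac_fragments$start) /
    sum(fx$chrom_sizes)
  occ <- oracle_tf(kept, fx$tf_peaks)
  list(region_id = kept$region_id,
       stability = oracle_assign(kept, fx$pg4s, st),
       phylop = oracle_assign(kept, fx$pg4s, ph),
       chrom_state = oracle_state(kept, fx$segmentation),
       atac = if (depth > 0) oracle_atac(kept, fx$atac_fragments, depth)
              else rep(0, nrow(kept)),
       occupancy = occ,
       recruitment = if (recruitment == "hits") as.integer(rowSums(occ))
                     else as.integer(rowSums(occ > 0L)))
}
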