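#' Pairwise Spearman correlation matrix of region metrics
#'
#' Complete-case pairwise Spearman rank correlations (mid-ranks for ties)
#' with large-sample t-approximation p-values.  Constant columns yield `NA`
#' with a warning.
#'
#' @param table region table (see [build_region_table()]).
#' @param metrics numeric column names to correlate; default the standard
#'   numeric metrics present in the table.
#' @return list of class `g4_cor_matrix` with symmetric matrices `rho`,
#'   `p_value` and `n` (pair counts); diagonal rho is 1.
#' @export
spearman_matrix <- function(table, metrics = NULL) {
  if (is.null(metrics))
    metrics <- intersect(c("stability", "eg4_signal", "atac", "phylop",
                           "tf_recruitment"), names(table))
  stopifnot(length(metrics) >= 2L, all(metrics %in% names(table)))
  k <- length(metrics)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(metrics, metrics))
  diag(rho) <- 1; diag(p) <- 0
  diag(n) <- vapply(metrics, function(m) sum(!is.na(table[[m]])), numeric(1))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      x <- table[[metrics[i]]]; y <- table[[metrics[j]]]
      cc <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(cc)
      if (sum(cc) < 3L) next
      if (stats::sd(x[cc]) == 0 || stats::sd(y[cc]) == 0) {
        warning("'", metrics[if (stats::sd(x[cc]) == 0) i else j],
                "' is constant; correlation undefined", call. = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[cc], y[cc], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p_value = p, n = n), class = "g4_cor_matrix")
}

#' @export
print.g4_cor_matrix <- function(x, ...) {
  cat("Spearman correlation matrix (complete pairwise cases):\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' Per-chromatin-state distribution summaries of a metric
#'
#' Groups the region table by chromatin state and reports n, median and
#' quartiles per state, ordered by the supplied state vocabulary (default
#' the 18-state set); states without regions appear with n = 0.  The TF
#' recruitment count is, by convention of the corresponding figure,
#' normalized by its maximum before summarizing (`normalize`).
#'
#' @param table region table with a `chrom_state` column.
#' @param metric numeric column to summarize.
#' @param states state vocabulary fixing the output order.
#' @param normalize divide by the maximum value first (default: only for
#'   `tf_recruitment`).
#' @return data.frame: `state`, `n`, `q1`, `median`, `q3`.
#' @export
state_distributions <- function(table, metric,
                                states = chromhmm18_states(),
                                normalize = identical(metric,
                                                      "tf_recruitment")) {
  stopifnot("chrom_state" %in% names(table), metric %in% names(table))
  v <- table[[metric]]
  if (normalize && any(!is.na(v)) && max(v, na.rm = TRUE) > 0)
    v <- v / max(v, na.rm = TRUE)
  out <- do.call(rbind, lapply(states, function(st) {
    x <- v[!is.na(v) & table$chrom_state == st]
    data.frame(state = st, n = length(x),
               q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' TSS-proximal eG4-to-gene assignments
#'
#' Pairs every gene with every eG4 region whose midpoint lies within
#' `window_bp` of the TSS (closed window on both ends: a midpoint exactly
#' at TSS +/- window_bp is included).  The signed distance is strand-aware:
#' positive means the region midpoint lies downstream of the TSS.  The
#' stability class is the cutoff binarization of the region's MM%.
#'
#' @param regions region table with `stability` (MM%) and `region_id`.
#' @param tss TSS data.frame (`chrom`, `pos`, `gene_id`, `strand`).
#' @param window_bp half-width of the window in bp (default 200).
#' @param stability_cutoff MM% cutoff for the High/Low class (default 25).
#' @return data.frame: `gene_id`, `region_id`, `distance`,
#'   `stability_class` (`NA` when the region's stability is missing).
#' @export
tss_proximal_assignments <- function(regions, tss, window_bp = 200L,
                                     stability_cutoff = 25) {
  stopifnot(all(c("chrom", "pos", "gene_id", "strand") %in% names(tss)))
  mid <- .midpoint(regions)
  out <- NULL
  for (t in seq_len(nrow(tss))) {
    sel <- which(regions$chrom == tss$chrom[t] &
                   mid >= tss$pos[t] - window_bp &
                   mid <= tss$pos[t] + window_bp)
    if (!length(sel)) next
    delta <- mid[sel] - tss$pos[t]
    if (tss$strand[t] == "-") delta <- -delta
    cls <- ifelse(is.na(regions$stability[sel]), NA_character_,
                  ifelse(regions$stability[sel] >= stability_cutoff,
                         "High", "Low"))
    out <- rbind(out, data.frame(
      gene_id = tss$gene_id[t],
      region_id = regions$region_id[sel],
      distance = as.integer(delta),
      stability_class = cls))
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(0), region_id = character(0),
                      distance = integer(0), stability_class = character(0))
  rownames(out) <- NULL
  out
}

#' Gene-level stability class from TSS assignments
#'
#' When several eG4 regions map to one gene the gene's class is that of the
#' nearest region (`"nearest"`, default; ties to the smaller absolute
#' distance then High) or "High if any assigned region is High"
#' (`"any-high"`).
#'
#' @param assignments output of [tss_proximal_assignments()].
#' @param multi_eg4 `"nearest"` or `"any-high"`.
#' @return data.frame `gene_id`, `stability_class`.
#' @export
gene_stability_classes <- function(assignments,
                                   multi_eg4 = c("nearest", "any-high")) {
  multi_eg4 <- match.arg(multi_eg4)
  a <- assignments[!is.na(assignments$stability_class), , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(gene_id = character(0), stability_class = character(0)))
  cls <- vapply(split(a, a$gene_id), function(d) {
    if (multi_eg4 == "any-high")
      return(if (any(d$stability_class == "High")) "High" else "Low")
    d <- d[order(abs(d$distance), d$stability_class != "High"), , drop = FALSE]
    d$stability_class[1]
  }, character(1))
  data.frame(gene_id = names(cls), stability_class = unname(cls))
}
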