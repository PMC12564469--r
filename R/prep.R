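#' Discretize a region table for structure learning
#'
#' Numeric metrics are split at their *cell-line-specific* (per-stratum)
#' median: "High" iff strictly greater than the stratum median (ties at the
#' median go "Low" by default; flip with `median_ties = "high"`).  The
#' stability metric (MM%) alone uses a fixed empirical cutoff instead of a
#' median: "High" iff MM% >= `stability_cutoff` (default 25).  The chromatin
#' state passes through as a categorical column.  Rows with a missing value
#' in any used column are dropped first, with a message reporting the count
#' -- the CI tests downstream require complete cases.
#'
#' @param table region table (one row per eG4 region) with a `stratum`
#'   column; see [build_region_table()].
#' @param stability_cutoff MM% threshold for the stability split.
#' @param median_ties `"low"` (default) or `"high"`: side to which values
#'   exactly at the stratum median are assigned.
#' @param metrics numeric columns to median-split; defaults to the standard
#'   set intersected with what is present (per-TF occupancy columns,
#'   `occ_*`, are included automatically when present).
#' @return data.frame of factor columns (levels `Low`, `High`; chromatin
#'   state keeps its own vocabulary) plus `stratum`.
#' @export
discretize <- function(table, stability_cutoff = 25,
                       median_ties = c("low", "high"),
                       metrics = NULL) {
  median_ties <- match.arg(median_ties)
  stopifnot("stratum" %in% names(table))
  if (is.null(metrics))
    metrics <- intersect(c("eg4_signal", "atac", "phylop", "tf_recruitment",
                           grep("^occ_", names(table), value = TRUE)),
                         names(table))
  used <- intersect(c("stability", metrics, "chrom_state"), names(table))
  cc <- stats::complete.cases(table[used])
  if (any(!cc))
    message("discretize: dropped ", sum(!cc),
            " incomplete row(s) of ", nrow(table))
  table <- table[cc, , drop = FALSE]
  for (st in unique(table$stratum))
    if (sum(table$stratum == st) < 2L)
      stop("stratum '", st, "' has fewer than 2 complete rows")

  out <- data.frame(row.names = seq_len(nrow(table)))
  hl <- function(x) factor(ifelse(x, "High", "Low"), levels = c("Low", "High"))
  if ("stability" %in% names(table))
    out$Stability <- hl(table$stability >= stability_cutoff)
  rename <- c(eg4_signal = "eG4s", atac = "ATACSig", phylop = "phyloP",
              tf_recruitment = "TFs")
  for (m in metrics) {
    med <- stats::ave(table[[m]], table$stratum,
                      FUN = function(v) stats::median(v))
    high <- if (median_ties == "low") table[[m]] > med else table[[m]] >= med
    nm <- if (m %in% names(rename)) rename[[m]] else m
    out[[nm]] <- hl(high)
  }
  if ("chrom_state" %in% names(table))
    out$ChromState <- factor(table$chrom_state)
  out$stratum <- table$stratum
  rownames(out) <- NULL
  out
}

#' Stratified sampling configuration
#'
#' @param strategy `"equal"` (fixed count per stratum) or `"proportional"`
#'   (fixed percentage per stratum).
#' @param k sample count per stratum (equal) or percentage in (0, 100]
#'   (proportional).
#' @param seed optional integer seed; when non-NULL [stratified_sample()]
#'   seeds the RNG itself.
#' @param replace sample with replacement?  Default `FALSE`: the study caps
#'   k at the smallest stratum, which implies without-replacement draws.
#' @return a list of class `g4_sampling_config`.
#' @export
sampling_config <- function(strategy = c("equal", "proportional"), k,
                            seed = NULL, replace = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  if (strategy == "proportional" && k > 100) stop("percentage k must be <= 100")
  structure(list(strategy = strategy, k = k, seed = seed, replace = replace),
            class = "g4_sampling_config")
}

#' Stratified sampling of a discrete table
#'
#' Draws rows independently within each stratum, without replacement by
#' default.  Equal allocation takes exactly `k` rows per stratum (error,
#' naming the stratum, if `k` exceeds its size); proportional allocation
#' takes `round(k% * stratum size)` rows, with R's round-half-even rounding.
#'
#' @param table data.frame with a `stratum` column.
#' @param config a [sampling_config()].
#' @return the sampled data.frame (row order: strata in order of first
#'   appearance, sampled rows in draw order).
#' @export
stratified_sample <- function(table, config) {
  stopifnot(inherits(config, "g4_sampling_config"),
            "stratum" %in% names(table))
  if (!is.null(config$seed)) set.seed(config$seed)
  strata <- unique(table$stratum)
  picks <- lapply(strata, function(st) {
    idx <- which(table$stratum == st)
    size <- if (config$strategy == "equal") config$k else
      round(config$k / 100 * length(idx))
    if (!config$replace && size > length(idx))
      stop("stratum '", st, "' has ", length(idx),
           " rows; cannot draw ", size, " without replacement")
    idx[sample.int(length(idx), size, replace = config$replace)]
  })
  out <- table[unlist(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}
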