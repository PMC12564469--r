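# Signal mapping: attach thermostability (MM%), conservation (phyloP),
# chromatin state, accessibility and TF occupancy to eG4 regions.  All
# coordinates are 0-based half-open; the midpoint of [s, e) is
# floor((s + e) / 2); the w bp window centred on position m is
# [m - w/2, m + w/2).

.midpoint <- function(df) (df$start + df$end) %/% 2L

# overlap hits between two 0-based half-open interval frames
.overlap_hits <- function(a, b) {
  # disjoint seqlevel sets (e.g. an empty or single-chromosome track) are a
  # legitimate no-overlap case, not worth a GenomicRanges warning
  h <- suppressWarnings(GenomicRanges::findOverlaps(.gr(a), .gr(b)))
  cbind(q = S4Vectors::queryHits(h), s = S4Vectors::subjectHits(h))
}

#' Keep eG4 regions containing at least one pG4 motif
#'
#' A region survives iff it overlaps (>= 1 bp, either strand) at least one
#' putative G4 locus; input order is preserved.  This is the motif filter
#' applied to consensus ChIP-Seq regions before any signal mapping.
#'
#' @param regions eG4 region data.frame (`chrom`, `start`, `end`, ...).
#' @param pg4s pG4 locus data.frame (`chrom`, `start`, `end`, `strand`).
#' @return the surviving subset of `regions`.
#' @export
filter_regions_with_pg4 <- function(regions, pg4s) {
  .check_intervals(regions, "region")
  if (nrow(regions) == 0L || nrow(pg4s) == 0L)
    return(regions[integer(0), , drop = FALSE])
  .check_intervals(pg4s, "pG4")
  hit <- unique(.overlap_hits(regions, pg4s)[, "q"])
  regions[sort(hit), , drop = FALSE]
}

# max/mean of a value track over per-locus windows, optionally strand-matched
.window_stat <- function(loci, track, width, stat, strand_match) {
  if (nrow(loci) == 0L)
    return(numeric(0))
  m <- .midpoint(loci)
  win <- data.frame(chrom = loci$chrom,
                    start = pmax(0L, m - width %/% 2L),
                    end = m + width %/% 2L)
  out <- rep(NA_real_, nrow(loci))
  if (nrow(track) == 0L) return(out)
  hits <- .overlap_hits(win, track)
  if (strand_match && nrow(hits))
    hits <- hits[loci$strand[hits[, "q"]] == track$strand[hits[, "s"]], ,
                 drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  if (stat == "max") {
    agg <- tapply(track$value[hits[, "s"]], hits[, "q"], max)
  } else {
    # per-base mean: weight each track interval by its overlap width
    ov_w <- pmin(win$end[hits[, "q"]], track$end[hits[, "s"]]) -
      pmax(win$start[hits[, "q"]], track$start[hits[, "s"]])
    num <- tapply(track$value[hits[, "s"]] * ov_w, hits[, "q"], sum)
    den <- tapply(ov_w, hits[, "q"], sum)
    agg <- num / den
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Thermostability (MM%) of pG4 loci
#'
#' Assigns each pG4 the maximum mismatch percentage from the *same strand*
#' within a 150 bp window centred on the locus midpoint; `NA` when no
#' same-strand MM% value covers the window.
#'
#' @param pg4s pG4 data.frame (`chrom`, `start`, `end`, `strand`).
#' @param mm_track strand-keyed MM% track: data.frame `chrom`, `start`,
#'   `end`, `value` (percent, in \[0, 100\]), `strand`.
#' @param window window width in bp (default 150).
#' @return numeric vector of MM% values (or `NA`), one per pG4.
#' @export
stability_of_pg4 <- function(pg4s, mm_track, window = 150L) {
  if (nrow(pg4s)) stopifnot(all(pg4s$strand %in% c("+", "-")))
  if (nrow(mm_track)) {
    stopifnot(all(mm_track$strand %in% c("+", "-")))
    if (any(mm_track$value < 0 | mm_track$value > 100))
      stop("MM% values must lie in [0, 100]")
  }
  .window_stat(pg4s, mm_track, window, "max", strand_match = TRUE)
}

#' Conservation (phyloP) of pG4 loci
#'
#' Mean phyloP score over the covered positions of a 50 bp window centred on
#' the locus midpoint, strand-agnostic; `NA` for uncovered windows.
#'
#' @param pg4s pG4 data.frame.
#' @param phylop_track data.frame `chrom`, `start`, `end`, `value`.
#' @param window window width in bp (default 50).
#' @return numeric vector, one value (or `NA`) per pG4.
#' @export
phylop_of_pg4 <- function(pg4s, phylop_track, window = 50L) {
  .window_stat(pg4s, phylop_track, window, "mean", strand_match = FALSE)
}

#' Assign a per-pG4 value to each region via the midpoint-nearest pG4
#'
#' Among the pG4s overlapping a region and carrying a (non-missing) value,
#' the one whose midpoint is closest to the region midpoint donates its
#' value; ties break to the lower start coordinate, then to the + strand.
#' `NA` when no overlapping pG4 carries a value.  `mode = "genomewide"`
#' relaxes the overlap restriction to the nearest valued pG4 on the same
#' chromosome (sensitivity analysis).
#'
#' @param regions region data.frame.
#' @param pg4s pG4 data.frame.
#' @param values numeric vector aligned with `pg4s` rows (e.g. from
#'   [stability_of_pg4()] or [phylop_of_pg4()]).
#' @param mode `"overlapping"` (default) or `"genomewide"`.
#' @return numeric vector, one value (or `NA`) per region.
#' @export
assign_region_value <- function(regions, pg4s, values,
                                mode = c("overlapping", "genomewide")) {
  mode <- match.arg(mode)
  stopifnot(length(values) == nrow(pg4s))
  out <- rep(NA_real_, nrow(regions))
  if (nrow(regions) == 0L || nrow(pg4s) == 0L) return(out)
  rmid <- .midpoint(regions)
  pmid <- .midpoint(pg4s)
  if (mode == "overlapping") {
    hits <- .overlap_hits(regions, pg4s)
  } else {
    qi <- rep(seq_len(nrow(regions)), each = nrow(pg4s))
    si <- rep(seq_len(nrow(pg4s)), nrow(regions))
    same <- regions$chrom[qi] == pg4s$chrom[si]
    hits <- cbind(q = qi[same], s = si[same])
  }
  if (nrow(hits) == 0L) return(out)
  keep <- !is.na(values[hits[, "s"]])
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  dist <- abs(pmid[hits[, "s"]] - rmid[hits[, "q"]])
  ord <- order(hits[, "q"], dist, pg4s$start[hits[, "s"]],
               pg4s$strand[hits[, "s"]] != "+")
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits[, "q"])
  out[hits[first, "q"]] <- values[hits[first, "s"]]
  out
}

#' Chromatin state at the region midpoint
#'
#' Looks up the segmentation label covering each region's midpoint (segments
#' are half-open, so a midpoint exactly at a boundary b of \[a,b) \[b,c)
#' belongs to \[b,c)).  `NA` where the midpoint is unsegmented.  Overlapping
#' segments are a validation error.
#'
#' @param regions region data.frame.
#' @param segmentation data.frame `chrom`, `start`, `end`, `state`.
#' @return character vector of state labels (or `NA`), one per region.
#' @export
chrom_state_of_region <- function(regions, segmentation) {
  .check_intervals(segmentation, "segmentation")
  o <- order(segmentation$chrom, segmentation$start)
  seg <- segmentation[o, , drop = FALSE]
  same <- seg$chrom[-1] == seg$chrom[-nrow(seg)]
  if (any(same & seg$start[-1] < seg$end[-nrow(seg)]))
    stop("segmentation contains overlapping segments")
  out <- rep(NA_character_, nrow(regions))
  if (nrow(regions) == 0L) return(out)
  m <- .midpoint(regions)
  pts <- data.frame(chrom = regions$chrom, start = m, end = m + 1L)
  hits <- .overlap_hits(pts, seg)
  out[hits[, "q"]] <- seg$state[hits[, "s"]]
  out
}

#' Normalized ATAC fragment coverage of regions
#'
#' Mean per-base fragment coverage of the region divided by the genome-wide
#' mean sequencing depth:
#' `(sum of fragment coverage over region positions / region length) /
#' mean_depth`.  When `mean_depth` is `NULL` it is computed from the
#' fragments as total fragment bases over the genome size given by
#' `chrom_sizes`.
#'
#' @param regions region data.frame.
#' @param fragments ATAC fragment intervals (`chrom`, `start`, `end`).
#' @param mean_depth average sequencing depth (> 0), or `NULL` to derive it.
#' @param chrom_sizes named vector of chromosome lengths; required when
#'   `mean_depth` is `NULL`.
#' @return numeric vector of normalized coverages, one per region.
#' @export
atac_intensity <- function(regions, fragments, mean_depth = NULL,
                           chrom_sizes = NULL) {
  if (is.null(mean_depth)) {
    if (is.null(chrom_sizes))
      stop("supply 'mean_depth' or 'chrom_sizes' to derive it")
    if (nrow(fragments) == 0L)       # no sequencing: coverage is 0 everywhere
      return(rep(0, nrow(regions)))
    mean_depth <- sum(as.numeric(fragments$end - fragments$start)) /
      sum(as.numeric(chrom_sizes))
  }
  if (!is.numeric(mean_depth) || mean_depth <= 0)
    stop("'mean_depth' must be > 0")
  out <- rep(0, nrow(regions))
  if (nrow(regions) == 0L || nrow(fragments) == 0L)
    return(out / mean_depth)
  hits <- .overlap_hits(regions, fragments)
  if (nrow(hits)) {
    ov <- pmin(regions$end[hits[, "q"]], fragments$end[hits[, "s"]]) -
      pmax(regions$start[hits[, "q"]], fragments$start[hits[, "s"]])
    cov_sum <- tapply(ov, hits[, "q"], sum)
    out[as.integer(names(cov_sum))] <- as.numeric(cov_sum)
  }
  (out / (regions$end - regions$start)) / mean_depth
}

#' TF occupancy and recruitment of regions
#'
#' Occupancy of a TF in a region is the number of that TF's peaks
#' overlapping the region; recruitment summarizes the region's TF load,
#' either as the total number of peak hits (`"hits"`, default) or as the
#' number of distinct TFs with at least one hit (`"distinct"`).  The two
#' readings are both plausible for the published definition, so the choice
#' is an explicit flag rather than a silent default.
#'
#' @param regions region data.frame.
#' @param tf_peaks peak data.frame `chrom`, `start`, `end`, `tf`.
#' @param recruitment `"hits"` or `"distinct"`.
#' @return list with `occupancy` (integer matrix regions x TFs) and
#'   `recruitment` (integer vector).
#' @export
tf_metrics <- function(regions, tf_peaks, recruitment = c("hits", "distinct")) {
  recruitment <- match.arg(recruitment)
  tfs <- sort(unique(as.character(tf_peaks$tf)))
  occ <- matrix(0L, nrow(regions), length(tfs),
                dimnames = list(NULL, tfs))
  if (nrow(regions) && nrow(tf_peaks)) {
    hits <- .overlap_hits(regions, tf_peaks)
    if (nrow(hits)) {
      tfi <- match(as.character(tf_peaks$tf[hits[, "s"]]), tfs)
      for (r in seq_len(nrow(hits)))
        occ[hits[r, "q"], tfi[r]] <- occ[hits[r, "q"], tfi[r]] + 1L
    }
  }
  rec <- if (recruitment == "hits") rowSums(occ) else rowSums(occ > 0L)
  list(occupancy = occ, recruitment = as.integer(rec))
}

#' Build the region-by-metric table
#'
#' Composes the full mapping stage: the pG4-containment filter, stability
#' and phyloP per pG4 then per region (midpoint-nearest assignment),
#' chromatin state at the midpoint, normalized ATAC coverage and TF
#' occupancy/recruitment.  Missing stability/phyloP values propagate as
#' `NA`; nothing is imputed.  A [make_genome_fixture()] object may be passed
#' as the single first argument.
#'
#' @param regions region data.frame with `eg4_signal` and `stratum` columns
#'   (or a `g4_fixture`).
#' @param pg4s,mm_track,phylop_track,segmentation,atac_fragments,tf_peaks
#'   the mapped tracks (see the per-metric functions); ignored when
#'   `regions` is a fixture.
#' @param chrom_sizes,mean_depth see [atac_intensity()].
#' @param recruitment see [tf_metrics()].
#' @param stability_window,phylop_window window widths in bp.
#' @param assign_mode see [assign_region_value()].
#' @return data.frame with one row per surviving region: `chrom`, `start`,
#'   `end`, `region_id`, `eg4_signal`, `stability`, `phylop`,
#'   `chrom_state`, `atac`, `tf_recruitment`, one `occ_<TF>` column per TF,
#'   and `stratum`.
#' @export
build_region_table <- function(regions, pg4s = NULL, mm_track = NULL,
                               phylop_track = NULL, segmentation = NULL,
                               atac_fragments = NULL, tf_peaks = NULL,
                               chrom_sizes = NULL, mean_depth = NULL,
                               recruitment = c("hits", "distinct"),
                               stability_window = 150L, phylop_window = 50L,
                               assign_mode = c("overlapping", "genomewide")) {
  if (inherits(regions, "g4_fixture")) {
    fx <- regions
    return(build_region_table(fx$regions, fx$pg4s, fx$mm_track,
                              fx$phylop_track, fx$segmentation,
                              fx$atac_fragments, fx$tf_peaks,
                              chrom_sizes = fx$chrom_sizes,
                              mean_depth = mean_depth,
                              recruitment = recruitment,
                              stability_window = stability_window,
                              phylop_window = phylop_window,
                              assign_mode = assign_mode))
  }
  recruitment <- match.arg(recruitment)
  assign_mode <- match.arg(assign_mode)
  stopifnot(all(c("eg4_signal", "stratum") %in% names(regions)))
  if (nrow(regions) && any(regions$eg4_signal < 0))
    stop("eG4 signal scores must be non-negative")

  kept <- filter_regions_with_pg4(regions, pg4s)
  pg4_stab <- stability_of_pg4(pg4s, mm_track, window = stability_window)
  pg4_phy <- phylop_of_pg4(pg4s, phylop_track, window = phylop_window)
  tfm <- tf_metrics(kept, tf_peaks, recruitment = recruitment)

  out <- data.frame(
    chrom = kept$chrom, start = kept$start, end = kept$end,
    region_id = if (!is.null(kept$region_id)) kept$region_id else
      sprintf("region_%04d", seq_len(nrow(kept))),
    eg4_signal = kept$eg4_signal,
    stability = assign_region_value(kept, pg4s, pg4_stab, mode = assign_mode),
    phylop = assign_region_value(kept, pg4s, pg4_phy, mode = assign_mode),
    chrom_state = chrom_state_of_region(kept, segmentation),
    atac = atac_intensity(kept, atac_fragments, mean_depth = mean_depth,
                          chrom_sizes = chrom_sizes),
    tf_recruitment = tfm$recruitment,
    stringsAsFactors = FALSE)
  if (ncol(tfm$occupancy)) {
    occ_df <- as.data.frame(tfm$occupancy)
    names(occ_df) <- paste0("occ_", colnames(tfm$occupancy))
    out <- cbind(out, occ_df)
  }
  out$stratum <- kept$stratum
  rownames(out) <- NULL
  out
}
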