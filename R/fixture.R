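#' Configuration of the toy genome fixture
#'
#' Parameters of [make_genome_fixture()].  The defaults describe a small
#' two-chromosome genome with three cell-line strata, dense enough that
#' every mapping rule (strand-matched windows, midpoint lookups, decoy
#' regions without pG4s) is exercised.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param strata stratum (cell line) labels; regions are generated per
#'   stratum.
#' @param n_regions eG4 regions per stratum (each is planted with pG4s).
#' @param n_decoys pG4-free decoy regions per stratum (removed by the
#'   containment filter downstream).
#' @param region_len,pg4_len,frag_len,peak_len,seg_len integer length ranges
#'   `c(min, max)` for the respective features.
#' @param pg4_per_region range of planted pG4s per region.
#' @param n_bg_pg4 background pG4s placed outside decoy regions.
#' @param mm_bin,mm_cover bin width and per-strand coverage probability of
#'   the MM% track (values uniform in \[0, 100\]).
#' @param phylop_bin,phylop_cover bin width and coverage probability of the
#'   phyloP track (values normal, mean 1, sd 1.5).
#' @param n_atac_frags ATAC fragments.
#' @param tf_names TF vocabulary; `peaks_per_tf` peaks each.
#' @param peaks_per_tf peaks per TF.
#' @param n_tss TSS records (`gene_<i>`, random strand).
#' @param states chromatin-state vocabulary used for the tiling
#'   segmentation.
#' @return a named list of class `g4_fixture_config`.
#' @export
fixture_config <- function(chrom_sizes = c(chrA = 30000L, chrB = 20000L),
                           strata = c("K562", "HepG2", "HEK293T"),
                           n_regions = 15L, n_decoys = 4L,
                           region_len = c(120L, 400L),
                           pg4_per_region = c(1L, 3L),
                           pg4_len = c(15L, 40L),
                           n_bg_pg4 = 30L,
                           mm_bin = 50L, mm_cover = 0.7,
                           phylop_bin = 25L, phylop_cover = 0.8,
                           seg_len = c(200L, 2000L),
                           n_atac_frags = 400L,
                           frag_len = c(80L, 300L),
                           tf_names = c("SP1", "SP2", "YY1", "TARDBP",
                                        "CTCF", "FOXA1"),
                           peaks_per_tf = 25L,
                           peak_len = c(50L, 200L),
                           n_tss = 30L,
                           states = chromhmm18_states()) {
  cfg <- as.list(environment())
  if (is.null(names(chrom_sizes))) stop("'chrom_sizes' must be named")
  if (max(region_len) + 10L > min(chrom_sizes))
    stop("chromosomes are too small for the requested region lengths")
  structure(cfg, class = "g4_fixture_config")
}

# uniform interval of length in `len_range` within a random chromosome
.rand_intervals <- function(n, chrom_sizes, len_range) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                  prob = chrom_sizes / sum(chrom_sizes))
  len <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  maxs <- chrom_sizes[chrom] - len
  if (any(maxs < 0)) stop("chromosome too small for a requested feature")
  start <- floor(stats::runif(n) * (maxs + 1))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), row.names = NULL)
}

# random full tiling of every chromosome with labelled segments
.rand_segmentation <- function(chrom_sizes, seg_len, states) {
  out <- NULL
  for (ch in names(chrom_sizes)) {
    pos <- 0L
    starts <- integer(0)
    while (pos < chrom_sizes[[ch]]) {
      starts <- c(starts, pos)
      pos <- pos + sample(seg_len[1]:seg_len[2], 1L)
    }
    ends <- c(starts[-1], chrom_sizes[[ch]])
    out <- rbind(out, data.frame(
      chrom = ch, start = starts, end = as.integer(ends),
      state = sample(states, length(starts), replace = TRUE)))
  }
  out
}

# binned track with partial coverage
.rand_track <- function(chrom_sizes, bin, cover, rvalue) {
  out <- NULL
  for (ch in names(chrom_sizes)) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = bin)
    keep <- stats::runif(length(starts)) < cover
    starts <- starts[keep]
    if (!length(starts)) next
    out <- rbind(out, data.frame(
      chrom = ch, start = starts,
      end = as.integer(pmin(starts + bin, chrom_sizes[[ch]])),
      value = rvalue(length(starts))))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0))
  out
}

.overlaps_any <- function(iv, others) {
  if (nrow(others) == 0L) return(rep(FALSE, nrow(iv)))
  hit <- .overlap_hits(iv, others)
  seq_len(nrow(iv)) %in% hit[, "q"]
}

#' Generate a toy genome fixture
#'
#' Builds a deterministic small-genome dataset exercising every mapping
#' rule: eG4 regions with significance scores per stratum (each containing
#' at least one planted pG4), pG4-free decoy regions, stranded MM% and
#' unstranded phyloP tracks, a full chromatin-state tiling, ATAC fragments,
#' named TF peaks and TSS records.  All intervals are 0-based half-open and
#' lie within the chromosome bounds; the same seed reproduces the same
#' fixture.
#'
#' @param seed integer RNG seed (mandatory).
#' @param config a [fixture_config()].
#' @return an object of class `g4_fixture`: list with `chrom_sizes`,
#'   `regions` (incl. decoys), `pg4s`, `mm_track`, `phylop_track`,
#'   `segmentation`, `atac_fragments`, `tf_peaks`, `tss` and `config`.
#' @examples
#' fx <- make_genome_fixture(1, fixture_config(n_regions = 4, n_decoys = 1))
#' head(fx$regions)
#' @export
make_genome_fixture <- function(seed, config = fixture_config()) {
  stopifnot(inherits(config, "g4_fixture_config"))
  set.seed(seed)
  cs <- config$chrom_sizes

  n_keep <- config$n_regions * length(config$strata)
  keepers <- .rand_intervals(n_keep, cs, config$region_len)
  keepers$stratum <- rep(config$strata, each = config$n_regions)

  # plant pG4s fully inside each keeper region
  planted <- NULL
  for (r in seq_len(nrow(keepers))) {
    k <- sample(config$pg4_per_region[1]:config$pg4_per_region[2], 1L)
    for (i in seq_len(k)) {
      len <- sample(config$pg4_len[1]:config$pg4_len[2], 1L)
      len <- min(len, keepers$end[r] - keepers$start[r])
      s <- keepers$start[r] +
        sample.int(keepers$end[r] - keepers$start[r] - len + 1L, 1L) - 1L
      planted <- rbind(planted, data.frame(
        chrom = keepers$chrom[r], start = s, end = s + len))
    }
  }

  # decoys: regions overlapping no planted pG4 (rejection sampling)
  decoys <- NULL
  n_dec <- config$n_decoys * length(config$strata)
  tries <- 0L
  while (NROW(decoys) < n_dec) {
    cand <- .rand_intervals(n_dec, cs, config$region_len)
    cand <- cand[!.overlaps_any(cand, planted), , drop = FALSE]
    decoys <- utils::head(rbind(decoys, cand), n_dec)
    tries <- tries + 1L
    if (tries > 200L)
      stop("could not place pG4-free decoy regions; genome too crowded")
  }
  if (n_dec > 0L)
    decoys$stratum <- rep(config$strata, each = config$n_decoys)

  # background pG4s: anywhere except inside decoy regions
  bg <- NULL
  if (config$n_bg_pg4 > 0L) {
    tries <- 0L
    while (NROW(bg) < config$n_bg_pg4) {
      cand <- .rand_intervals(config$n_bg_pg4, cs, config$pg4_len)
      if (n_dec > 0L)
        cand <- cand[!.overlaps_any(cand, decoys), , drop = FALSE]
      bg <- utils::head(rbind(bg, cand), config$n_bg_pg4)
      tries <- tries + 1L
      if (tries > 200L)
        stop("could not place background pG4s; genome too crowded")
    }
  }
  pg4s <- rbind(planted, bg)
  pg4s$strand <- sample(c("+", "-"), nrow(pg4s), replace = TRUE)
  pg4s$score <- round(stats::runif(nrow(pg4s), 20, 80), 2)

  regions <- rbind(keepers, if (n_dec > 0L) decoys)
  regions$eg4_signal <- round(stats::rexp(nrow(regions), rate = 1 / 60), 3)
  regions$region_id <- sprintf("eG4_%04d", seq_len(nrow(regions)))

  mm_plus <- .rand_track(cs, config$mm_bin, config$mm_cover,
                         function(n) round(stats::runif(n, 0, 100), 2))
  mm_minus <- .rand_track(cs, config$mm_bin, config$mm_cover,
                          function(n) round(stats::runif(n, 0, 100), 2))
  mm_plus$strand <- rep("+", nrow(mm_plus))
  mm_minus$strand <- rep("-", nrow(mm_minus))
  mm_track <- rbind(mm_plus, mm_minus)

  phylop_track <- .rand_track(cs, config$phylop_bin, config$phylop_cover,
                              function(n) round(stats::rnorm(n, 1, 1.5), 3))
  segmentation <- .rand_segmentation(cs, config$seg_len, config$states)
  atac_fragments <- .rand_intervals(config$n_atac_frags, cs, config$frag_len)

  n_tf <- length(config$tf_names) * config$peaks_per_tf
  tf_peaks <- .rand_intervals(n_tf, cs, config$peak_len)
  if (n_tf > 0L)
    tf_peaks$tf <- rep(config$tf_names, each = config$peaks_per_tf)
  else tf_peaks$tf <- character(0)

  tss_chrom <- sample(names(cs), config$n_tss, replace = TRUE)
  tss <- data.frame(
    chrom = tss_chrom,
    pos = as.integer(floor(stats::runif(config$n_tss) * cs[tss_chrom])),
    gene_id = sprintf("gene_%03d", seq_len(config$n_tss)),
    strand = sample(c("+", "-"), config$n_tss, replace = TRUE),
    row.names = NULL)

  structure(list(chrom_sizes = cs, regions = regions, pg4s = pg4s,
                 mm_track = mm_track, phylop_track = phylop_track,
                 segmentation = segmentation,
                 atac_fragments = atac_fragments, tf_peaks = tf_peaks,
                 tss = tss, config = config),
            class = "g4_fixture")
}

#' @export
print.g4_fixture <- function(x, ...) {
  cat("Toy genome fixture:", sum(x$chrom_sizes), "bp over",
      length(x$chrom_sizes), "chromosome(s)\n")
  cat("  regions:", nrow(x$regions), " pG4s:", nrow(x$pg4s),
      " TF peaks:", nrow(x$tf_peaks), " TSS:", nrow(x$tss), "\n")
  invisible(x)
}

#' Export / re-import a fixture as plain-text genomic files
#'
#' Writes one BED per stratum for the eG4 regions (name = region id,
#' score = eG4 signal), the pG4 loci as GFF3, the MM% track as one bedGraph
#' per strand, phyloP as bedGraph, the segmentation / ATAC fragments / TF
#' peaks as BED (feature name = state or TF), and the TSS list as TSV.
#' `read_fixture()` loads such a directory back into a `g4_fixture`
#' (chromosome sizes are stored in `chrom_sizes.tsv`).
#'
#' @param fixture a `g4_fixture`.
#' @param dir output directory (created if needed).
#' @return `write_fixture`: `dir`, invisibly; `read_fixture`: a
#'   `g4_fixture`.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "g4_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_table_tsv(data.frame(chrom = names(fixture$chrom_sizes),
                             size = as.integer(fixture$chrom_sizes)),
                  p("chrom_sizes.tsv"))
  for (st in unique(fixture$regions$stratum)) {
    r <- fixture$regions[fixture$regions$stratum == st, , drop = FALSE]
    write_bed(data.frame(chrom = r$chrom, start = r$start, end = r$end,
                         name = r$region_id, score = r$eg4_signal),
              p(paste0("regions_", st, ".bed")))
  }
  write_pg4_gff3(fixture$pg4s, p("pg4.gff3"))
  mm <- fixture$mm_track
  write_bedgraph(mm[mm$strand == "+", c("chrom", "start", "end", "value")],
                 p("mm_plus.bedGraph"))
  write_bedgraph(mm[mm$strand == "-", c("chrom", "start", "end", "value")],
                 p("mm_minus.bedGraph"))
  write_bedgraph(fixture$phylop_track, p("phylop.bedGraph"))
  seg <- fixture$segmentation
  write_bed(data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                       name = seg$state), p("segmentation.bed"))
  write_bed(fixture$atac_fragments, p("atac_fragments.bed"))
  tp <- fixture$tf_peaks
  write_bed(data.frame(chrom = tp$chrom, start = tp$start, end = tp$end,
                       name = tp$tf), p("tf_peaks.bed"))
  write_tss(fixture$tss, p("tss.tsv"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  p <- function(...) file.path(dir, ...)
  sizes <- read_table_tsv(p("chrom_sizes.tsv"))
  cs <- stats::setNames(as.integer(sizes$size), sizes$chrom)
  region_files <- list.files(dir, pattern = "^regions_.*\\.bed$",
                             full.names = TRUE)
  regions <- do.call(rbind, lapply(region_files, function(f) {
    st <- sub("^regions_(.*)\\.bed$", "\\1", basename(f))
    b <- read_bed(f)
    data.frame(chrom = b$chrom, start = b$start, end = b$end,
               stratum = st, eg4_signal = b$score, region_id = b$name)
  }))
  mm_p <- read_bedgraph(p("mm_plus.bedGraph"))
  mm_m <- read_bedgraph(p("mm_minus.bedGraph"))
  mm_p$strand <- rep("+", nrow(mm_p))
  mm_m$strand <- rep("-", nrow(mm_m))
  seg <- read_bed(p("segmentation.bed"))
  tp <- read_bed(p("tf_peaks.bed"))
  structure(list(
    chrom_sizes = cs, regions = regions,
    pg4s = read_pg4_gff3(p("pg4.gff3")),
    mm_track = rbind(mm_p, mm_m),
    phylop_track = read_bedgraph(p("phylop.bedGraph")),
    segmentation = data.frame(chrom = seg$chrom, start = seg$start,
                              end = seg$end, state = seg$name),
    atac_fragments = read_bed(p("atac_fragments.bed"))[
      c("chrom", "start", "end")],
    tf_peaks = data.frame(chrom = tp$chrom, start = tp$start, end = tp$end,
                          tf = tp$name),
    tss = read_tss(p("tss.tsv")), config = NULL), class = "g4_fixture")
}
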