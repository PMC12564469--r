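# Readers/writers for the small set of genomic text formats the pipeline
# consumes.  Internally every interval is 0-based half-open in a plain
# data.frame (chrom/start/end); conversion to and from the 1-based closed
# GRanges convention happens only here and in the overlap helpers.

# data.frame (0-based half-open) -> GRanges
.gr <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}

# GRanges -> data.frame (0-based half-open)
.df_from_gr <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

.check_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start < 0)) stop(what, ": negative start coordinate")
  if (nrow(df) && any(df$start >= df$end))
    stop(what, ": start must be < end (0-based half-open)")
  invisible(df)
}

#' Read/write BED intervals
#'
#' BED3/BED6 with optional name/score/strand columns; coordinates stay in
#' the native 0-based half-open convention.
#'
#' @param path file path.
#' @return `read_bed`: data.frame with columns `chrom`, `start`, `end` and,
#'   when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- .df_from_gr(gr)
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) df$name <- md$name
  if ("score" %in% names(md)) df$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' @param df interval data.frame (0-based half-open; optional `name`,
#'   `score`, `strand` columns).
#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  .check_intervals(df, "BED")
  gr <- .gr(df, strand = df$strand)
  if (!is.null(df$name)) gr$name <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write bedGraph tracks
#'
#' @param path file path.
#' @return `read_bedgraph`: data.frame `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- .df_from_gr(gr)
  df$value <- gr$score
  df
}

#' @param df data.frame `chrom`, `start`, `end`, `value`.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(df, path) {
  .check_intervals(df, "bedGraph")
  gr <- .gr(df)
  gr$score <- df$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write pG4 loci as GFF3
#'
#' The motif-finder output convention: one feature per putative G4, strand
#' mandatory, an optional numeric motif score.  GFF3's 1-based closed
#' coordinates are converted to 0-based half-open on read.
#'
#' @param path file path.
#' @return `read_pg4_gff3`: data.frame `chrom`, `start`, `end`, `strand`
#'   and optional `score`.
#' @export
read_pg4_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- .df_from_gr(gr)
  df$strand <- as.character(GenomicRanges::strand(gr))
  if (!all(df$strand %in% c("+", "-")))
    stop("pG4 loci must carry +/- strands")
  if (!is.null(gr$score)) df$score <- as.numeric(gr$score)
  df
}

#' @param df data.frame with `chrom`, `start`, `end`, `strand` (+/-) and
#'   optional `score`.
#' @rdname read_pg4_gff3
#' @export
write_pg4_gff3 <- function(df, path) {
  .check_intervals(df, "pG4")
  stopifnot(all(df$strand %in% c("+", "-")))
  gr <- .gr(df, strand = df$strand)
  gr$source <- "g4causal"
  gr$type <- "sequence_feature"
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write TSS lists
#'
#' Tab-separated with header `chrom`, `pos`, `gene_id`, `strand`; `pos` is
#' the 0-based TSS coordinate.
#'
#' @param path file path.
#' @return `read_tss`: the data.frame.
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "gene_id", "strand") %in% names(df)))
  df
}

#' @param df TSS data.frame.
#' @rdname read_tss
#' @export
write_tss <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write generic TSV tables (region tables, discrete tables)
#'
#' @param path file path.
#' @return `read_table_tsv`: the data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param df any data.frame.
#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
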