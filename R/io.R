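# File I/O at the package boundary. BED and bedGraph go through
# rtracklayer; sparse matrices through Matrix (MatrixMarket). Coordinates in
# files follow each format's convention; in memory everything is 0-based
# half-open.

#' Read pre-miRNA coordinates from a BED6 file
#'
#' @param file BED6 path (name in column 4, strand in column 6).
#' @return data.frame with `name`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_premirna_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  data.frame(name = if (!is.null(gr$name)) gr$name else
               paste0("mir_", seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read CAGE TSS evidence from a scored BED file
#'
#' Each record is a single-base feature; the BED score column carries the
#' CAGE tag count.
#'
#' @param file BED path.
#' @return data.frame with `chrom`, `position` (0-based), `strand`, `score`.
#' @export
read_cage_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr) - 1L,
             strand = as.character(GenomicRanges::strand(gr)),
             score = if (!is.null(gr$score)) as.numeric(gr$score) else 1,
             stringsAsFactors = FALSE)
}

#' Read a per-strand coverage track from a bedGraph file
#'
#' Expands interval records into a per-base vector over the covered span of
#' one chromosome. bedGraph does not carry strand, so the strand of the
#' track is supplied by the caller (the convention used throughout: one file
#' per strand).
#'
#' @param file bedGraph path.
#' @param chrom chromosome to extract.
#' @param strand strand label to attach to the track.
#' @return coverage track: list with `chrom`, `strand`, `start`, `values`.
#' @export
read_bedgraph_track <- function(file, chrom, strand) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  if (length(gr) == 0L)
    return(list(chrom = chrom, strand = strand, start = 0L, values = numeric(0)))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  lo <- min(s); hi <- max(e)
  values <- numeric(hi - lo)
  for (i in seq_along(gr))
    values[(s[i] - lo + 1L):(e[i] - lo)] <- gr$score[i]
  list(chrom = chrom, strand = strand, start = lo, values = values)
}

#' Write a coverage track as bedGraph
#'
#' Run-length compresses the per-base vector; zero runs are omitted.
#'
#' @param track coverage track (see [read_bedgraph_track()]).
#' @param file output path.
#' @export
write_bedgraph_track <- function(track, file) {
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  df <- data.frame(chrom = track$chrom,
                   start = track$start + starts[keep],
                   end = track$start + ends[keep],
                   score = r$values[keep])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Write a BED6 file from a data.frame of named intervals
#'
#' @param df data.frame with `name`, `chrom`, `start`, `end`, `strand` and
#'   optionally `score` (default 0); 0-based half-open, written unchanged.
#' @param file output path.
#' @export
write_bed6 <- function(df, file) {
  score <- if ("score" %in% names(df)) df$score else 0
  out <- data.frame(df$chrom, df$start, df$end, df$name, score, df$strand)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a cell count matrix from an MTX directory
#'
#' Expects `matrix.mtx`, `features.tsv` (columns: feature id, feature type)
#' and `barcodes.tsv`, the layout written by [write_matrix_dir()].
#'
#' @param dir directory path.
#' @return a cell count matrix: list with `counts` (dgCMatrix, features x
#'   barcodes), `features` (data.frame `feature_id`, `feature_type`) and
#'   `barcodes` (character).
#' @export
read_matrix_dir <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feat <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  names(feat)[1:2] <- c("feature_id", "feature_type")
  bc <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(feat$feature_id, bc)
  list(counts = counts, features = feat[, 1:2], barcodes = bc)
}

#' Write a cell count matrix to an MTX directory
#'
#' @param mat cell count matrix (see [read_matrix_dir()]).
#' @param dir output directory (created if needed).
#' @export
write_matrix_dir <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat$counts, file.path(dir, "matrix.mtx"))
  write.table(mat$features, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mat$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
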