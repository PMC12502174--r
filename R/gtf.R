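#' Emit a custom GTF for miRNA gene loci
#'
#' Each locus yields one `gene` line, one `transcript` line and one `exon`
#' line spanning the full locus (the single-exon pri-miRNA model), plus one
#' additional transcript (with its exon chain) per alternative transcript
#' structure. Internal 0-based half-open coordinates are converted to the
#' 1-based inclusive GTF convention. Records are sorted by chrom then start;
#' transcript ids are `<gene_id>.t1`, `.t2`, ... and the attribute
#' `gene_type "miRNA_gene"` marks every record.
#'
#' @param loci list of loci from [build_mirna_loci()] / [summarize_locus()].
#' @param file optional path; when given the lines are written there.
#' @return character vector of GTF lines, invisibly when `file` is set.
#' @export
emit_gtf <- function(loci, file = NULL) {
  ids <- vapply(loci, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id in loci", call. = FALSE)
  ord <- order(vapply(loci, `[[`, "", "chrom"), vapply(loci, `[[`, 0L, "start"))
  lines <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, attrs)
    paste(chrom, "mirgene", feat, start0 + 1L, end0, ".", strand, ".",
          attrs, sep = "\t")
  for (loc in loci[ord]) {
    ga <- sprintf('gene_id "%s"; gene_type "miRNA_gene";', loc$gene_id)
    lines <- c(lines, fmt(loc$chrom, "gene", loc$start, loc$end, loc$strand, ga))
    tids <- paste0(loc$gene_id, ".t", seq_len(1L + length(loc$alt_transcripts)))
    ta <- function(tid)
      sprintf('gene_id "%s"; transcript_id "%s"; gene_type "miRNA_gene";',
              loc$gene_id, tid)
    # primary single-exon pri-miRNA transcript
    lines <- c(lines,
               fmt(loc$chrom, "transcript", loc$start, loc$end, loc$strand,
                   ta(tids[1L])),
               fmt(loc$chrom, "exon", loc$start, loc$end, loc$strand, ta(tids[1L])))
    for (k in seq_along(loc$alt_transcripts)) {
      ex <- loc$alt_transcripts[[k]]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (any(ex$start[-1] < ex$end[-nrow(ex)]))
        stop("alt transcript exons overlap in locus ", loc$gene_id, call. = FALSE)
      tid <- tids[k + 1L]
      lines <- c(lines,
                 fmt(loc$chrom, "transcript", min(ex$start), max(ex$end),
                     loc$strand, ta(tid)))
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, fmt(loc$chrom, "exon", ex$start[j], ex$end[j],
                              loc$strand, ta(tid)))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a miRNA gene GTF back into loci
#'
#' Parses a GTF produced by [emit_gtf()] (via `rtracklayer`) and rebuilds
#' the locus list: interval, strand, gene id and alternative transcript exon
#' chains. Member pre-miRNAs are not stored in the GTF and come back empty.
#'
#' @param file path to a GTF file.
#' @return list of loci ordered by chrom then start.
#' @export
read_mirna_gtf <- function(file) {
  gr <- rtracklayer::import(file, format = "gff2")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   transcript_id = if (!is.null(gr$transcript_id))
                     gr$transcript_id else NA_character_,
                   stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", , drop = FALSE]
  loci <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    loc <- list(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                end = g$end, strand = g$strand,
                members = .interval_df(character(0), integer(0), integer(0),
                                       character(0)),
                locus_class = NA_character_, host_gene_id = NA_character_,
                alt_transcripts = list())
    tids <- unique(df$transcript_id[df$type == "transcript" &
                                      df$gene_id == g$gene_id])
    tids <- sort(tids)
    for (tid in tids[-1L]) {           # .t1 is the primary single-exon model
      ex <- df[df$type == "exon" & !is.na(df$transcript_id) &
                 df$transcript_id == tid, c("chrom", "start", "end", "strand")]
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      loc$alt_transcripts <- c(loc$alt_transcripts, list(ex))
    }
    loci[[i]] <- loc
  }
  ord <- order(genes$chrom, genes$start)
  loci[ord]
}

#' Write miRNA gene loci as BED6
#'
#' @param loci list of loci.
#' @param file output path; BED is 0-based half-open so coordinates are
#'   written unchanged. Score column holds the number of member pre-miRNAs.
#' @export
write_loci_bed <- function(loci, file) {
  df <- data.frame(
    chrom = vapply(loci, `[[`, "", "chrom"),
    start = vapply(loci, `[[`, 0L, "start"),
    end = vapply(loci, `[[`, 0L, "end"),
    name = vapply(loci, `[[`, "", "gene_id"),
    score = vapply(loci, function(l) nrow(l$members), 0L),
    strand = vapply(loci, `[[`, "", "strand"))
  df <- df[order(df$chrom, df$start), ]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
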