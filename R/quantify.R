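# UMI counting over miRNA gene loci from tagged SAM alignments.
#
# SAM text is parsed in-package (tab fields, CIGAR walk, CB/UB-style tags);
# only reference-consuming operations matter here: M/=/X and D fall inside
# an aligned block, N splits blocks (spliced alignment), I/S/H/P consume no
# reference. Since a locus is a single exon spanning its introns, any block
# overlap assigns the read (intron-inclusive counting).

#' Parse a tagged SAM text file
#'
#' @param file SAM path (text; headers ignored).
#' @param cb_tag,umi_tag two-letter tag names carrying the cell barcode and
#'   UMI (defaults `CB`/`UB`). A missing UMI tag is allowed (plate-seq).
#' @return list with `reads` (data.frame: `read_id`, `chrom`, `strand`,
#'   `cell_barcode`, `umi`) and `blocks` (data.frame: `read` index into
#'   `reads`, `start`, `end`; 0-based half-open).
#' @export
read_tagged_sam <- function(file, cb_tag = "CB", umi_tag = "UB") {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(list(reads = data.frame(read_id = character(0), chrom = character(0),
                                   strand = character(0),
                                   cell_barcode = character(0),
                                   umi = character(0)),
                blocks = data.frame(read = integer(0), start = integer(0),
                                    end = integer(0))))
  f <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(f, `[[`, "", i)
  qname <- getf(1L)
  flag <- as.integer(getf(2L))
  rname <- getf(3L)
  pos <- as.integer(getf(4L))            # 1-based leftmost
  cigar <- getf(6L)
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  strand <- ifelse(bitwAnd(flag, 16L) == 0L, "+", "-")
  tagval <- function(tag) {
    pre <- paste0(tag, ":Z:")
    vapply(f, function(x) {
      hit <- x[startsWith(x, pre)]
      if (length(hit)) substring(hit[1L], 6L) else NA_character_
    }, "")
  }
  cb <- tagval(cb_tag)
  umi <- tagval(umi_tag)
  reads <- data.frame(read_id = qname, chrom = rname, strand = strand,
                      cell_barcode = cb, umi = umi,
                      stringsAsFactors = FALSE)[mapped, , drop = FALSE]
  blocks <- .cigar_blocks(cigar[mapped], pos[mapped])
  list(reads = reads, blocks = blocks)
}

# CIGAR -> aligned reference blocks (0-based half-open), vectorized over
# reads; `pos` is the 1-based SAM POS.
.cigar_blocks <- function(cigar, pos) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  out_read <- integer(0); out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(cigar)) {
    m <- regmatches(cigar[i], ops[i])[[1L]]
    len <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- substring(m, nchar(m))
    ref <- pos[i] - 1L                   # 0-based cursor
    bs <- integer(0); be <- integer(0)
    open_s <- NA_integer_
    for (k in seq_along(op)) {
      o <- op[k]
      if (o %in% c("M", "=", "X", "D")) {
        if (is.na(open_s)) open_s <- ref
        ref <- ref + len[k]
      } else if (o == "N") {
        if (!is.na(open_s)) { bs <- c(bs, open_s); be <- c(be, ref) }
        open_s <- NA_integer_
        ref <- ref + len[k]
      }                                  # I/S/H/P: no reference consumed
    }
    if (!is.na(open_s)) { bs <- c(bs, open_s); be <- c(be, ref) }
    out_read <- c(out_read, rep.int(i, length(bs)))
    out_s <- c(out_s, bs); out_e <- c(out_e, be)
  }
  data.frame(read = out_read, start = out_s, end = out_e)
}

#' Assign tagged alignments to miRNA gene loci
#'
#' A read is assigned to a locus when any aligned block overlaps the locus
#' interval (the single-exon locus spans its introns, so intronic reads
#' count). In stranded mode the alignment strand must match the locus
#' strand. Reads overlapping more than one qualifying locus are ambiguous
#' and left unassigned.
#'
#' @param aln parsed alignments from [read_tagged_sam()].
#' @param loci list of loci ([build_mirna_loci()] or [read_mirna_gtf()]).
#' @param stranded require strand match (default TRUE; FALSE for strandless
#'   plate-seq chemistry).
#' @return character vector, one element per read: the assigned `gene_id`
#'   or `NA` (unassigned or ambiguous).
#' @export
assign_alignments <- function(aln, loci, stranded = TRUE) {
  n <- nrow(aln$reads)
  n_hits <- integer(n)
  hit_id <- rep(NA_character_, n)
  for (loc in loci) {
    ok_block <- aln$blocks$start < loc$end & aln$blocks$end > loc$start
    rd <- unique(aln$blocks$read[ok_block])
    rd <- rd[aln$reads$chrom[rd] == loc$chrom]
    if (stranded) rd <- rd[aln$reads$strand[rd] == loc$strand]
    n_hits[rd] <- n_hits[rd] + 1L
    hit_id[rd] <- loc$gene_id
  }
  ifelse(n_hits == 1L, hit_id, NA_character_)
}

#' Count UMIs (or reads) per locus and cell barcode
#'
#' Droplet mode collapses PCR duplicates: the count is the number of
#' distinct (cell barcode, UMI) pairs per (locus, barcode). Plate mode (no
#' UMIs) counts assigned reads. Reads without a cell barcode are skipped and
#' reported via a message and the `n_skipped` attribute.
#'
#' @param assignments data.frame with `cell_barcode`, `umi`, `locus_id`
#'   (rows with `NA` locus are ignored).
#' @param mode `"droplet"` (UMI dedup) or `"plate"` (read counts).
#' @param barcodes optional barcode universe fixing the column set/order;
#'   default: barcodes observed among assigned reads, sorted.
#' @param feature_ids optional feature universe fixing the row set/order.
#' @return cell count matrix (list with `counts`, `features`, `barcodes`);
#'   feature type is `"miRNA_gene"`.
#' @export
count_umis <- function(assignments, mode = c("droplet", "plate"),
                       barcodes = NULL, feature_ids = NULL) {
  mode <- match.arg(mode)
  a <- assignments[!is.na(assignments$locus_id), , drop = FALSE]
  no_cb <- is.na(a$cell_barcode) | a$cell_barcode == ""
  if (any(no_cb)) {
    message(sum(no_cb), " assigned reads lacked a cell barcode and were skipped")
  }
  n_skipped <- sum(no_cb)
  a <- a[!no_cb, , drop = FALSE]
  if (mode == "droplet") {
    dt <- data.table::as.data.table(a[, c("cell_barcode", "umi", "locus_id")])
    dt <- unique(dt)
    tab <- dt[, .N, by = c("locus_id", "cell_barcode")]
  } else {
    dt <- data.table::as.data.table(a[, c("cell_barcode", "locus_id")])
    tab <- dt[, .N, by = c("locus_id", "cell_barcode")]
  }
  if (is.null(barcodes)) barcodes <- sort(unique(tab$cell_barcode))
  if (is.null(feature_ids)) feature_ids <- sort(unique(tab$locus_id))
  tab <- tab[tab$cell_barcode %in% barcodes & tab$locus_id %in% feature_ids, ]
  counts <- Matrix::sparseMatrix(
    i = match(tab$locus_id, feature_ids),
    j = match(tab$cell_barcode, barcodes),
    x = tab$N, dims = c(length(feature_ids), length(barcodes)),
    dimnames = list(feature_ids, barcodes))
  out <- list(counts = counts,
              features = data.frame(feature_id = feature_ids,
                                    feature_type = "miRNA_gene",
                                    stringsAsFactors = FALSE),
              barcodes = barcodes)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Count a tagged SAM file over miRNA gene loci
#'
#' Convenience wrapper chaining [read_tagged_sam()], [assign_alignments()]
#' and [count_umis()].
#'
#' @inheritParams read_tagged_sam
#' @inheritParams assign_alignments
#' @inheritParams count_umis
#' @return cell count matrix (see [count_umis()]).
#' @export
count_tagged_alignments <- function(file, loci, stranded = TRUE,
                                    mode = c("droplet", "plate"),
                                    cb_tag = "CB", umi_tag = "UB",
                                    barcodes = NULL, feature_ids = NULL) {
  aln <- read_tagged_sam(file, cb_tag = cb_tag, umi_tag = umi_tag)
  locus_id <- assign_alignments(aln, loci, stranded = stranded)
  count_umis(data.frame(cell_barcode = aln$reads$cell_barcode,
                        umi = aln$reads$umi, locus_id = locus_id,
                        stringsAsFactors = FALSE),
             mode = mode, barcodes = barcodes, feature_ids = feature_ids)
}

#' Merge a miRNA gene count matrix into a default gene matrix
#'
#' Appends the miRNA features below the default features. The barcode set
#' of the default matrix (the cell-called set) defines the columns: miRNA
#' counts are aligned by matching barcode, zero-filled where a default
#' barcode is absent from the miRNA matrix, and barcodes present only in
#' the miRNA matrix are dropped. Default-matrix values are never altered.
#'
#' @param default_mx,mirna_mx cell count matrices (see [read_matrix_dir()]).
#' @return merged cell count matrix.
#' @export
merge_matrices <- function(default_mx, mirna_mx) {
  if (any(mirna_mx$features$feature_id %in% default_mx$features$feature_id))
    stop("feature_id collision between default and miRNA matrices",
         call. = FALSE)
  bc <- default_mx$barcodes
  idx <- match(bc, mirna_mx$barcodes)
  mir <- Matrix::Matrix(0, nrow = nrow(mirna_mx$counts), ncol = length(bc),
                        sparse = TRUE)
  present <- !is.na(idx)
  mir[, present] <- mirna_mx$counts[, idx[present], drop = FALSE]
  counts <- rbind(default_mx$counts, mir)
  dimnames(counts) <- list(c(default_mx$features$feature_id,
                             mirna_mx$features$feature_id), bc)
  list(counts = as(counts, "CsparseMatrix"),
       features = rbind(default_mx$features, mirna_mx$features),
       barcodes = bc)
}
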