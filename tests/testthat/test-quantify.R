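sam_line <- function(id, flag, chrom, pos1, cigar, cb = NULL, umi = NULL) {
  tags <- c(if (!is.null(cb)) paste0("CB:Z:", cb),
            if (!is.null(umi)) paste0("UB:Z:", umi))
  paste(c(id, flag, chrom, pos1, 255, cigar, "*", 0, 0, "*", "*", tags),
        collapse = "\t")
}

write_sam_tmp <- function(lines) {
  tf <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000", lines), tf)
  tf
}

test_that("SAM parsing extracts strand, tags and CIGAR blocks", {
  tf <- write_sam_tmp(c(
    sam_line("r1", 0, "chr1", 101, "50M", "AAA", "U1"),
    sam_line("r2", 16, "chr1", 201, "20M100N30M", "BBB", "U2"),
    sam_line("r3", 0, "chr1", 301, "10M5D10M3I20M2S", "CCC", "U3"),
    sam_line("r4", 4, "*", 0, "*", "DDD", "U4")))       # unmapped: dropped
  aln <- read_tagged_sam(tf)
  expect_equal(nrow(aln$reads), 3)
  expect_equal(aln$reads$strand, c("+", "-", "+"))
  expect_equal(aln$reads$cell_barcode, c("AAA", "BBB", "CCC"))
  b1 <- aln$blocks[aln$blocks$read == 1, ]
  expect_equal(c(b1$start, b1$end), c(100, 150))
  b2 <- aln$blocks[aln$blocks$read == 2, ]              # N splits the block
  expect_equal(b2$start, c(200, 320))
  expect_equal(b2$end, c(220, 350))
  b3 <- aln$blocks[aln$blocks$read == 3, ]              # D within, I/S ignored
  expect_equal(c(b3$start, b3$end), c(300, 345))
})

test_that("alignment assignment respects strand and ambiguity rules", {
  loci <- list(make_locus("L1", "chr1", 100, 900, "+"),
               make_locus("L2", "chr1", 850, 2000, "+"),
               make_locus("L3", "chr1", 5000, 6000, "-"))
  tf <- write_sam_tmp(c(
    sam_line("in_l1", 0, "chr1", 201, "50M", "A", "U1"),
    sam_line("anti_l1", 16, "chr1", 201, "50M", "A", "U2"),
    sam_line("ambig", 0, "chr1", 861, "30M", "A", "U3"),
    sam_line("in_l3", 16, "chr1", 5101, "50M", "A", "U4"),
    sam_line("outside", 0, "chr1", 30001, "50M", "A", "U5")))
  aln <- read_tagged_sam(tf)
  stranded <- assign_alignments(aln, loci, stranded = TRUE)
  expect_equal(stranded, c("L1", NA, NA, "L3", NA))
  loose <- assign_alignments(aln, loci, stranded = FALSE)
  expect_equal(loose[2], "L1")            # antisense counts when strandless
  expect_true(is.na(loose[3]))            # ambiguity holds either way
})

test_that("UMI counting deduplicates in droplet mode and not in plate mode", {
  a <- data.frame(cell_barcode = c("A", "A", "A", "A", "B"),
                  umi = c("u1", "u1", "u1", "u2", "u1"),
                  locus_id = "L1", stringsAsFactors = FALSE)
  drop <- count_umis(a, "droplet")
  expect_equal(as.numeric(drop$counts["L1", c("A", "B")]), c(2, 1))
  plate <- count_umis(a, "plate")
  expect_equal(as.numeric(plate$counts["L1", c("A", "B")]), c(4, 1))
  # reads without a barcode are skipped, with an accounting message
  a$cell_barcode[5] <- NA
  expect_message(res <- count_umis(a, "droplet"), "skipped")
  expect_equal(attr(res, "n_skipped"), 1L)
  expect_false("B" %in% res$barcodes)
})

test_that("counting is order-independent and conserves assigned molecules", {
  set.seed(31)
  ann <- sim_annotation(1, 2)
  al <- sim_alignments(ann, n_reads = 3000, n_cells = 20, dup_rate = 0.4)
  tf <- tempfile(fileext = ".sam")
  write_sam(al$sam, tf)
  loci <- lapply(seq_len(nrow(ann$truth)), function(i)
    make_locus(ann$truth$gene_id[i], ann$truth$chrom[i], ann$truth$start[i],
               ann$truth$end[i], ann$truth$strand[i]))
  mx <- count_tagged_alignments(tf, loci)
  # conservation: total equals distinct (CB, UMI, locus) triples
  expect_equal(sum(mx$counts), sum(al$truth_counts$count))
  # exactness against the generator's truth table
  got <- mapply(function(l, c) mx$counts[l, c],
                al$truth_counts$locus_id, al$truth_counts$cell_barcode)
  expect_equal(unname(got), al$truth_counts$count)
  # shuffling the read lines yields an identical matrix
  body <- al$sam[!startsWith(al$sam, "@")]
  set.seed(1)
  tf2 <- tempfile(fileext = ".sam")
  writeLines(c(al$sam[startsWith(al$sam, "@")], sample(body)), tf2)
  mx2 <- count_tagged_alignments(tf2, loci)
  expect_equal(mx2$counts[rownames(mx$counts), colnames(mx$counts)],
               mx$counts)
})

test_that("matrix merging appends miRNA features without touching defaults", {
  set.seed(8)
  def <- list(counts = as(Matrix::Matrix(matrix(rpois(30, 4), 10, 3),
                                         sparse = TRUE), "CsparseMatrix"),
              features = data.frame(feature_id = paste0("g", 1:10),
                                    feature_type = "coding"),
              barcodes = c("A", "B", "C"))
  dimnames(def$counts) <- list(def$features$feature_id, def$barcodes)
  mir <- list(counts = as(Matrix::Matrix(matrix(rpois(12, 2), 4, 3),
                                         sparse = TRUE), "CsparseMatrix"),
              features = data.frame(feature_id = paste0("mir", 1:4),
                                    feature_type = "miRNA_gene"),
              barcodes = c("B", "C", "D"))     # D is not a called cell
  dimnames(mir$counts) <- list(mir$features$feature_id, mir$barcodes)
  merged <- merge_matrices(def, mir)
  expect_equal(dim(merged$counts), c(14L, 3L))
  expect_equal(merged$barcodes, c("A", "B", "C"))
  # default block unchanged
  expect_equal(as.matrix(merged$counts[1:10, ]), as.matrix(def$counts))
  # miRNA block aligned by barcode, zero where absent
  expect_equal(as.numeric(merged$counts["mir2", "B"]),
               as.numeric(mir$counts["mir2", "B"]))
  expect_equal(sum(merged$counts[11:14, "A"]), 0)
  # column sums add up
  expect_equal(Matrix::colSums(merged$counts)[c("B", "C")],
               Matrix::colSums(def$counts)[c("B", "C")] +
                 Matrix::colSums(mir$counts)[c("B", "C")])
  # feature collision is an error
  bad <- mir; bad$features$feature_id[1] <- "g1"
  dimnames(bad$counts)[[1]][1] <- "g1"
  expect_error(merge_matrices(def, bad), "collision")
})

test_that("matrix directories round-trip through MTX", {
  set.seed(9)
  mx <- list(counts = as(Matrix::Matrix(matrix(rpois(20, 1), 5, 4),
                                        sparse = TRUE), "CsparseMatrix"),
             features = data.frame(feature_id = paste0("f", 1:5),
                                   feature_type = c(rep("coding", 3),
                                                    rep("miRNA_gene", 2))),
             barcodes = paste0("BC", 1:4))
  dimnames(mx$counts) <- list(mx$features$feature_id, mx$barcodes)
  d <- tempfile()
  write_matrix_dir(mx, d)
  back <- read_matrix_dir(d)
  expect_equal(as.matrix(back$counts), as.matrix(mx$counts))
  expect_equal(back$features, mx$features)
  expect_equal(back$barcodes, mx$barcodes)
})
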