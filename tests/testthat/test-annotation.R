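iv <- function(chrom, start, end, strand)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)

test_that("reconcile keeps the longer of candidate and overlapping annotation", {
  cand <- iv("chr1", 100, 500, "+")
  expect_equal(reconcile_with_annotation(cand, iv("chr1", 150, 900, "+")),
               iv("chr1", 150, 900, "+"))
  expect_equal(reconcile_with_annotation(cand, NULL), cand)
  expect_equal(reconcile_with_annotation(cand, cand[0, ]), cand)
  # longer candidate wins over a shorter overlapping annotation
  expect_equal(reconcile_with_annotation(iv("chr1", 100, 900, "+"),
                                         iv("chr1", 150, 400, "+")),
               iv("chr1", 100, 900, "+"))
  # non-overlapping annotation is ignored
  expect_equal(reconcile_with_annotation(cand, iv("chr1", 600, 2000, "+")),
               cand)
  # brute force over random overlapping pairs: result length is never below
  # the candidate's, and always equals one of the two inputs
  set.seed(41)
  for (i in 1:50) {
    s1 <- sample(0:500, 1); e1 <- s1 + sample(50:400, 1)
    s2 <- sample(0:500, 1); e2 <- s2 + sample(50:400, 1)
    got <- reconcile_with_annotation(iv("c", s1, e1, "+"), iv("c", s2, e2, "+"))
    expect_gte(got$end - got$start, e1 - s1)
    expect_true((got$start == s1 && got$end == e1) ||
                  (got$start == s2 && got$end == e2))
  }
})

test_that("reconcile rejects mismatched chrom or strand", {
  cand <- iv("chr1", 100, 500, "+")
  expect_error(reconcile_with_annotation(cand, iv("chr2", 150, 900, "+")),
               "chrom")
  expect_error(reconcile_with_annotation(cand, iv("chr1", 150, 900, "-")),
               "strand")
})

test_that("refine_tss moves the 5' end to the strongest CAGE peak", {
  cand <- iv("chr1", 100, 800, "+")
  cage1 <- data.frame(chrom = "chr1", position = 90, strand = "+", score = 50)
  expect_equal(refine_tss(cand, cage1, 500), iv("chr1", 90, 800, "+"))
  expect_equal(refine_tss(cand, cage1[0, ], 500), cand)
  # far-away peak ignored
  expect_equal(refine_tss(cand, data.frame(chrom = "chr1", position = 5000,
                                           strand = "+", score = 99), 500),
               cand)
  # argmax by score, not proximity
  cage2 <- data.frame(chrom = "chr1", position = c(95, 120),
                      strand = "+", score = c(10, 40))
  expect_equal(refine_tss(cand, cage2, 500), iv("chr1", 120, 800, "+"))
  # score tie broken toward the original 5' end
  cage3 <- data.frame(chrom = "chr1", position = c(80, 110),
                      strand = "+", score = c(40, 40))
  expect_equal(refine_tss(cand, cage3, 500)$start, 110)
})

test_that("refine_tss is strand-aware and never moves the 3' end", {
  cand <- iv("chr1", 100, 800, "-")          # 5' end at position 799
  cage <- data.frame(chrom = "chr1", position = 900, strand = "-", score = 5)
  got <- refine_tss(cand, cage, 500)
  expect_equal(got, iv("chr1", 100, 901, "-"))
  set.seed(7)
  for (i in 1:20) {
    st <- sample(c("+", "-"), 1)
    cand <- iv("chr1", 1000, 3000, st)
    cage <- data.frame(chrom = "chr1",
                       position = sample(500:3500, 3),
                       strand = st, score = sample(1:100, 3))
    got <- refine_tss(cand, cage, 500)
    if (st == "+") expect_equal(got$end, 3000) else expect_equal(got$start, 1000)
  }
  # refinement that would invert the interval errors out
  expect_error(refine_tss(iv("chr1", 100, 120, "-"),
                          data.frame(chrom = "chr1", position = 50,
                                     strand = "-", score = 9), 500),
               "invert")
})

test_that("change-point extension finds a noiseless step exactly", {
  trk <- make_track("chr1", "+", 1300, high = 10, step_at = 800)
  got <- extend_end_changepoint(iv("chr1", 100, 400, "+"), trk,
                                search_span = 1000)
  expect_equal(got, iv("chr1", 100, 800, "+"))
  # constant signal: no change point, full extension
  flat <- make_track("chr1", "+", 3000, high = 10)
  got <- extend_end_changepoint(iv("chr1", 100, 400, "+"), flat,
                                search_span = 1000, min_drop_fraction = 0.2)
  expect_equal(got$end, 1400)
  # already at the step: end unchanged
  got <- extend_end_changepoint(iv("chr1", 100, 800, "+"), trk,
                                search_span = 400)
  expect_equal(got$end, 800)
})

test_that("change-point extension mirrors correctly on the minus strand", {
  # signal occupies [500, 2000) on the minus strand; candidate 3' end (start)
  # at 1200 should walk back to 500
  v <- rep(0, 2500); v[501:2000] <- 10
  trk <- list(chrom = "chr1", strand = "-", start = 0L, values = v)
  got <- extend_end_changepoint(iv("chr1", 1200, 2000, "-"), trk,
                                search_span = 1000)
  expect_equal(got, iv("chr1", 500, 2000, "-"))
})

test_that("change-point extension locates a noisy step within 25 bp", {
  set.seed(101)
  hits <- 0L
  for (i in 1:40) {
    trk <- make_track("chr1", "+", 2000, high = 10, low = 1, step_at = 800,
                      noise_sd = 1)
    got <- extend_end_changepoint(iv("chr1", 100, 400, "+"), trk,
                                  search_span = 1000)
    if (abs(got$end - 800) <= 25) hits <- hits + 1L
  }
  expect_gte(hits, 38)
  # exhaustive minimization cross-check on one draw
  set.seed(5)
  trk <- make_track("chr1", "+", 1600, high = 10, low = 1, step_at = 800,
                    noise_sd = 1)
  v <- trk$values[401:1400]
  cost <- vapply(0:1000, function(j) {
    a <- v[seq_len(j)]; b <- v[setdiff(seq_along(v), seq_len(j))]
    (if (j > 0) sum((a - mean(a))^2) else 0) +
      (if (j < 1000) sum((b - mean(b))^2) else 0)
  }, 0)
  got <- extend_end_changepoint(iv("chr1", 100, 400, "+"), trk,
                                search_span = 1000)
  expect_equal(got$end, 400 + (which.min(cost) - 1L))
})

test_that("change-point extension validates its coverage input", {
  trk <- make_track("chr1", "+", 300, high = 10)
  expect_error(extend_end_changepoint(iv("chr1", 100, 400, "+"), trk, 1000),
               "coverage")
  wrong <- make_track("chr2", "+", 2000, high = 10)
  expect_error(extend_end_changepoint(iv("chr1", 100, 400, "+"), wrong, 1000),
               "match")
})

test_that("summarize_locus spans most distal TSS to longest end", {
  members <- data.frame(name = "mir-x", chrom = "c", start = 300, end = 380,
                        strand = "+", stringsAsFactors = FALSE)
  loc <- summarize_locus(iv("c", c(100, 150), c(500, 900), "+"), members)
  expect_equal(c(loc$start, loc$end), c(100, 900))
  expect_equal(loc$strand, "+")
  # single transcript: identity
  loc1 <- summarize_locus(iv("c", 250, 500, "+"), members)
  expect_equal(c(loc1$start, loc1$end), c(250, 500))
  # minus strand: most distal TSS is the max end, span is still [min, max)
  mm <- data.frame(name = "mir-y", chrom = "c", start = 210, end = 290,
                   strand = "-", stringsAsFactors = FALSE)
  loc2 <- summarize_locus(iv("c", c(200, 100), c(600, 450), "-"), mm)
  expect_equal(c(loc2$start, loc2$end), c(100, 600))
  # brute-force union bound on random inputs
  set.seed(13)
  for (i in 1:30) {
    n <- sample(1:4, 1)
    s <- sample(0:900, n, replace = TRUE)
    tr <- iv("c", s, s + sample(100:400, n, replace = TRUE), "+")
    mem <- data.frame(name = "m", chrom = "c", start = min(tr$start),
                      end = min(tr$start) + 50, strand = "+",
                      stringsAsFactors = FALSE)
    tr <- rbind(tr, iv("c", mem$start, mem$end + 10, "+"))
    keep <- tr$start < mem$end & tr$end > mem$start
    loc <- summarize_locus(tr[keep, ], mem)
    expect_equal(loc$start, min(tr$start[keep]))
    expect_equal(loc$end, max(tr$end[keep]))
  }
})

test_that("summarize_locus enforces its preconditions", {
  members <- data.frame(name = "m", chrom = "c", start = 300, end = 380,
                        strand = "+", stringsAsFactors = FALSE)
  expect_error(summarize_locus(iv("c", 1, 2, "+")[0, ], members), "no transcripts")
  expect_error(summarize_locus(iv("c", c(100, 700), c(500, 900), "+"),
                               members), "overlaps no member")
  out <- data.frame(name = "m2", chrom = "c", start = 950, end = 990,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(summarize_locus(iv("c", 100, 500, "+"),
                               rbind(members, out)), "outside")
})

test_that("classification requires same-strand containment of the hairpin", {
  loc <- make_locus("mir-a", "c", 1000, 4000, "+",
                    members = data.frame(name = "mir-a", chrom = "c",
                                         start = 2000, end = 2100,
                                         strand = "+"))
  host <- data.frame(gene_id = "HostA", chrom = "c", start = 500, end = 6000,
                     strand = "+", stringsAsFactors = FALSE)
  got <- classify_locus(loc, host)
  expect_equal(got$locus_class, "intragenic")
  expect_equal(got$host_gene_id, "HostA")
  # no gene overlap
  got <- classify_locus(loc, host[0, ])
  expect_equal(got$locus_class, "intergenic")
  expect_true(is.na(got$host_gene_id))
  # antisense gene only: intergenic
  anti <- transform(host, strand = "-")
  expect_equal(classify_locus(loc, anti)$locus_class, "intergenic")
  # tie among hosts broken by larger overlap with the locus, then gene_id
  hosts <- data.frame(gene_id = c("B", "A"), chrom = "c",
                      start = c(500, 1900), end = c(6000, 4100),
                      strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_locus(loc, hosts)$host_gene_id, "B")
  hosts_eq <- data.frame(gene_id = c("B", "A"), chrom = "c",
                         start = c(900, 900), end = c(4100, 4100),
                         strand = "+", stringsAsFactors = FALSE)
  expect_equal(classify_locus(loc, hosts_eq)$host_gene_id, "A")
})

test_that("classification agrees with exhaustive containment enumeration", {
  set.seed(23)
  for (i in 1:30) {
    ms <- sample(0:2000, 1); me <- ms + 100
    loc <- make_locus("m", "c", ms - 200, me + 500, "+",
                      members = data.frame(name = "m", chrom = "c",
                                           start = ms, end = me,
                                           strand = "+"))
    genes <- data.frame(gene_id = paste0("G", 1:4), chrom = "c",
                        start = sample(0:2000, 4),
                        strand = sample(c("+", "-"), 4, replace = TRUE),
                        stringsAsFactors = FALSE)
    genes$end <- genes$start + sample(100:1500, 4)
    expected <- any(genes$strand == "+" & genes$start <= ms & me <= genes$end)
    got <- classify_locus(loc, genes)
    expect_equal(got$locus_class == "intragenic", expected)
  }
})

test_that("GTF emission uses 1-based inclusive coordinates and round-trips", {
  loc <- make_locus("mir-a", "chr1", 100, 900, "+")
  lines <- emit_gtf(list(loc))
  expect_length(lines, 3)
  exon <- strsplit(lines[3], "\t")[[1]]
  expect_equal(exon[3], "exon")
  expect_equal(as.integer(exon[4]), 101)
  expect_equal(as.integer(exon[5]), 900)
  expect_match(lines[1], 'gene_id "mir-a"')
  expect_match(lines[1], 'gene_type "miRNA_gene"')
  # one 2-exon alternative structure adds a transcript line + 2 exon lines
  alt <- list(data.frame(chrom = "chr1", start = c(100, 600),
                         end = c(200, 900), strand = "+"))
  loc2 <- make_locus("mir-b", "chr1", 100, 900, "+", alt = alt)
  expect_length(emit_gtf(list(loc2)), 6)
  expect_error(emit_gtf(list(loc, loc)), "duplicate")

  tf <- tempfile(fileext = ".gtf")
  emit_gtf(list(loc, loc2), tf)
  back <- read_mirna_gtf(tf)
  expect_equal(vapply(back, `[[`, "", "gene_id"), c("mir-a", "mir-b"))
  for (k in 1:2) {
    expect_equal(back[[k]]$start, 100)
    expect_equal(back[[k]]$end, 900)
    expect_equal(back[[k]]$strand, "+")
  }
  expect_length(back[[1]]$alt_transcripts, 0)
  expect_equal(back[[2]]$alt_transcripts[[1]]$start, c(100, 600))
  expect_equal(back[[2]]$alt_transcripts[[1]]$end, c(200, 900))
})

test_that("overlapping same-strand candidates merge into one clustered locus", {
  pm <- data.frame(name = c("mir-27b", "mir-23b"), chrom = "c",
                   start = c(1000, 1500), end = c(1100, 1600), strand = "+",
                   stringsAsFactors = FALSE)
  trk <- list(make_track("c", "+", 6000, high = 10, step_at = 2500))
  loci <- build_mirna_loci(pm, cage = NULL, tracks = trk,
                          search_span = 3000, window = 200)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$gene_id, "mir-23b~mir-27b")
  expect_equal(loci[[1]]$end, 2500)
  # an antisense pre-miRNA at the same position stays separate
  pm2 <- rbind(pm, data.frame(name = "mir-x", chrom = "c", start = 1200,
                              end = 1300, strand = "-"))
  trk2 <- c(trk, list(make_track("c", "-", 6000, high = 10)))
  loci2 <- build_mirna_loci(pm2, cage = NULL, tracks = trk2,
                           search_span = 1000, window = 200)
  expect_length(loci2, 2)
})
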