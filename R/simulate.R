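# Synthetic-data generators with full ground truth. Each generator is
# deterministic given the session RNG state (callers set.seed); the truth
# objects they return are sufficient to score every downstream module
# without re-simulation.

#' Generate a toy genome annotation with known miRNA gene loci
#'
#' Lays out miRNA gene loci along one toy chromosome in fixed-width slots,
#' alternating strand. Each locus is seeded by one pre-miRNA hairpin; the
#' true locus span starts 50-400 bp upstream of the hairpin (the TSS) and
#' ends 2-8 kb downstream (the primary-transcript end). Intragenic loci get
#' a same-strand host gene whose two terminal exons flank the locus, so the
#' hairpin sits in an intron; intergenic loci stand alone.
#'
#' @param n_intragenic,n_intergenic number of loci of each class.
#' @param slot_width genomic width reserved per locus (default 20000).
#' @param chrom_len chromosome length; defaults to just fitting all slots.
#'   Too small a value is a packing error.
#' @return list with `premirna` (data.frame: `name`, `chrom`, `start`,
#'   `end`, `strand`), `genes` (host gene bodies), `exons` (host exons),
#'   `truth` (data.frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `locus_class`, `host_gene_id`) and `chrom_len`.
#' @export
sim_annotation <- function(n_intragenic = 3L, n_intergenic = 3L,
                           slot_width = 20000L, chrom_len = NULL) {
  n <- n_intragenic + n_intergenic
  stopifnot(n >= 1L)
  need <- n * slot_width + 10000L
  if (is.null(chrom_len)) chrom_len <- need
  if (chrom_len < need)
    stop("chrom_len too small to pack ", n, " loci", call. = FALSE)
  classes <- sample(rep(c("intragenic", "intergenic"),
                        c(n_intragenic, n_intergenic)))
  pm <- tr <- list(); genes <- exons <- list()
  for (i in seq_len(n)) {
    slot <- (i - 1L) * slot_width + 5000L
    strand <- if (i %% 2L == 1L) "+" else "-"
    pre_len <- sample(70:110, 1L)
    tss_off <- sample(50:400, 1L)
    end_off <- sample(2000:8000, 1L)
    if (strand == "+") {
      ps <- slot + 3000L; pe <- ps + pre_len
      ls <- ps - tss_off; le <- pe + end_off
    } else {
      pe <- slot + slot_width - 6000L; ps <- pe - pre_len
      le <- pe + tss_off; ls <- ps - end_off
    }
    name <- sprintf("mir-%d", i)
    pm[[i]] <- data.frame(name = name, chrom = "chrS", start = ps, end = pe,
                          strand = strand, stringsAsFactors = FALSE)
    host <- NA_character_
    if (classes[i] == "intragenic") {
      host <- sprintf("Host%d", i)
      gs <- ls - 1000L; ge <- le + 1000L
      genes[[length(genes) + 1L]] <-
        data.frame(gene_id = host, chrom = "chrS", start = gs, end = ge,
                   strand = strand, stringsAsFactors = FALSE)
      exons[[length(exons) + 1L]] <-
        data.frame(gene_id = host, chrom = "chrS",
                   start = c(gs, ge - 200L), end = c(gs + 200L, ge),
                   strand = strand, stringsAsFactors = FALSE)
    }
    tr[[i]] <- data.frame(gene_id = name, chrom = "chrS", start = ls,
                          end = le, strand = strand, locus_class = classes[i],
                          host_gene_id = host, stringsAsFactors = FALSE)
  }
  list(premirna = do.call(rbind, pm),
       genes = if (length(genes)) do.call(rbind, genes) else
         data.frame(gene_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0)),
       exons = if (length(exons)) do.call(rbind, exons) else NULL,
       truth = do.call(rbind, tr), chrom_len = chrom_len)
}

#' Generate coverage tracks and CAGE evidence from truth loci
#'
#' Coverage on each strand is a step function equal to `signal` over every
#' truth locus span plus Gaussian noise (clamped at zero); CAGE places one
#' peak of score 50 at each truth 5' end (jittered by at most
#' `cage_jitter` bases) and a decoy peak of score 10 another 150 bases
#' into the locus body, so TSS refinement must pick the argmax, not the
#' nearest tag.
#'
#' @param ann annotation from [sim_annotation()] (its `truth` and
#'   `chrom_len` are used).
#' @param signal plateau height of the transcription signal (default 10).
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (default 0).
#' @param cage_jitter maximum absolute TSS jitter in bases (default 0,
#'   capped at 5).
#' @return list with `tracks` (two coverage tracks, one per strand) and
#'   `cage` (data.frame: `chrom`, `position`, `strand`, `score`).
#' @export
sim_tracks <- function(ann, signal = 10, noise_sd = 0, cage_jitter = 0L) {
  truth <- ann$truth
  cage_jitter <- min(as.integer(cage_jitter), 5L)
  tracks <- list()
  for (strand in c("+", "-")) {
    v <- numeric(ann$chrom_len)
    t <- truth[truth$strand == strand, , drop = FALSE]
    for (i in seq_len(nrow(t)))
      v[(t$start[i] + 1L):t$end[i]] <- v[(t$start[i] + 1L):t$end[i]] + signal
    if (noise_sd > 0) v <- pmax(v + rnorm(length(v), 0, noise_sd), 0)
    tracks[[length(tracks) + 1L]] <-
      list(chrom = "chrS", strand = strand, start = 0L, values = v)
  }
  fp <- .five_prime(truth$start, truth$end, truth$strand)
  jit <- if (cage_jitter > 0)
    sample(seq(-cage_jitter, cage_jitter), nrow(truth), replace = TRUE)
  else 0L
  into <- ifelse(truth$strand == "+", 150L, -150L)
  cage <- data.frame(
    chrom = "chrS", position = c(fp + jit, fp + into),
    strand = rep(truth$strand, 2L),
    score = rep(c(50, 10), each = nrow(truth)), stringsAsFactors = FALSE)
  list(tracks = tracks, cage = cage)
}

#' Generate tagged alignments over truth loci with known counts
#'
#' Draws molecules — distinct (locus, cell, UMI) triples — then samples
#' reads from them with replacement so a fraction of reads are PCR
#' duplicates. Read positions are uniform within the locus span (many are
#' intronic relative to any host-gene structure, by construction). A
#' fraction of reads can be flipped to the antisense strand; these are
#' excluded from the stranded truth table. The truth table records the
#' deduplicated counts implied by the emitted reads.
#'
#' @param ann annotation from [sim_annotation()].
#' @param n_reads total reads to emit (default 10000).
#' @param n_cells number of cell barcodes (default 50).
#' @param dup_rate expected fraction of reads that are duplicates of an
#'   already-emitted molecule (default 0.5).
#' @param antisense_frac fraction of reads flipped to the opposite strand
#'   (default 0).
#' @param read_len aligned length per read (default 90).
#' @return list with `sam` (character vector of SAM lines including
#'   header), `truth_counts` (data.frame: `locus_id`, `cell_barcode`,
#'   `count` — stranded, deduplicated) and `barcodes`.
#' @export
sim_alignments <- function(ann, n_reads = 10000L, n_cells = 50L,
                           dup_rate = 0.5, antisense_frac = 0,
                           read_len = 90L) {
  truth <- ann$truth
  barcodes <- sprintf("CB%04d", seq_len(n_cells))
  n_mol <- max(1L, round(n_reads * (1 - dup_rate)))
  mol <- data.frame(
    locus = sample(seq_len(nrow(truth)), n_mol, replace = TRUE),
    cell = sample(seq_len(n_cells), n_mol, replace = TRUE))
  mol$umi <- sprintf("U%08d", seq_len(n_mol))   # globally unique molecules
  # every molecule is emitted at least once; the remaining reads are PCR
  # duplicates drawn uniformly, so dup_rate 0 means one read per molecule
  pick <- c(seq_len(n_mol),
            if (n_reads > n_mol)
              sample(seq_len(n_mol), n_reads - n_mol, replace = TRUE))
  li <- mol$locus[pick]
  span <- truth$end[li] - truth$start[li] - read_len
  pos0 <- truth$start[li] + floor(runif(n_reads) * pmax(span, 1L))
  strand <- truth$strand[li]
  anti <- runif(n_reads) < antisense_frac
  strand[anti] <- ifelse(strand[anti] == "+", "-", "+")
  flag <- ifelse(strand == "-", 16L, 0L)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:chrS\tLN:%d", ann$chrom_len),
    sprintf("r%06d\t%d\tchrS\t%d\t255\t%dM\t*\t0\t0\t*\t*\tCB:Z:%s\tUB:Z:%s",
            seq_len(n_reads), flag, pos0 + 1L, read_len,
            barcodes[mol$cell[pick]], mol$umi[pick]))
  sense <- !anti
  dt <- data.table::data.table(
    locus_id = truth$gene_id[li[sense]],
    cell_barcode = barcodes[mol$cell[pick[sense]]],
    umi = mol$umi[pick[sense]])
  tc <- unique(dt)[, .N, by = c("locus_id", "cell_barcode")]
  truth_counts <- data.frame(locus_id = tc$locus_id,
                             cell_barcode = tc$cell_barcode, count = tc$N,
                             stringsAsFactors = FALSE)
  truth_counts <- truth_counts[order(truth_counts$locus_id,
                                     truth_counts$cell_barcode), ]
  rownames(truth_counts) <- NULL
  list(sam = lines, truth_counts = truth_counts, barcodes = barcodes)
}

# sample NB conditioned on being positive; mu may be a vector
.rnbinom_pos <- function(n, mu, size) {
  mu <- rep_len(mu, n)
  x <- rnbinom(n, mu = mu, size = size)
  while (any(x == 0)) {
    z <- x == 0
    x[z] <- rnbinom(sum(z), mu = mu[z], size = size)
  }
  x
}

#' Simulate a count matrix with spiked differential-distribution effects
#'
#' Background genes follow a negative binomial whose mean scales with each
#' cell's depth factor, thinned by depth-dependent dropout (logistic in log
#' depth) — identical in both groups, so any call on them is a false
#' positive. Spiked genes control detection and expression directly:
#'
#' * `DZ`: detection Bernoulli(`dz_rates[1]`) in group 1 vs `dz_rates[2]`
#'   in group 2; expressing cells share one NB mode.
#' * `DE`: equal detection; the positive-count mean is shifted by
#'   `de_lfc` log2 units in group 2.
#' * `DP`: equal detection; positive counts come from a low/high NB mode
#'   pair with low-mode weight `dp_weights[1]` vs `dp_weights[2]`.
#' * `DM`: group 1 is an even two-mode mixture, group 2 has the low mode
#'   only.
#'
#' @param n_genes background (null) coding genes (default 200).
#' @param n_cells integer vector: cells in group 1 and group 2.
#' @param n_spike named integer vector with entries `DZ`, `DE`, `DP`, `DM`
#'   (default one of each; set to 0s for a pure null).
#' @param n_mirna_null miRNA-typed features with no effect (default 16);
#'   together with the spiked genes they form the tested feature set, the
#'   coding background serving normalization — the usual arrangement when a
#'   small family of loci is tested against a transcriptome-wide backdrop.
#' @param depth_meanlog,depth_sdlog log-normal cell depth factor parameters.
#' @param mu_meanlog,mu_sdlog log-normal per-gene baseline mean parameters.
#' @param theta_shape per-gene NB size drawn log-normal around this value
#'   with 10% jitter; dispersion varies smoothly with abundance, the regime
#'   that pooling dispersion estimates across similar genes assumes.
#' @param dropout add depth-dependent dropout to background genes.
#' @param dz_rates,de_lfc,de_rate,dp_weights,dm_rate,pos_mu,pos_theta,
#'   mode_mu,mode_theta spiked-effect parameters (see above; `mode_mu` is
#'   the low/high NB mode mean pair and `mode_theta` the NB size of the
#'   mode components — tight enough that the two modes are separated by
#'   several standard deviations on the log2 scale, the regime the DP/DM
#'   categories describe).
#' @return list with `counts` (cell count matrix list: spiked features are
#'   typed `miRNA_gene`, background `coding`), `meta` (data.frame:
#'   `barcode`, `group`, `nCount`) and `truth` (data.frame: `gene_id`,
#'   `category`).
#' @export
sim_counts <- function(n_genes = 200L, n_cells = c(300L, 300L),
                       n_spike = c(DZ = 1L, DE = 1L, DP = 1L, DM = 1L),
                       n_mirna_null = 16L,
                       depth_meanlog = log(2000), depth_sdlog = 0.35,
                       mu_meanlog = log(1.5), mu_sdlog = 1.1,
                       theta_shape = 1.5, dropout = TRUE,
                       dz_rates = c(0.6, 0.2), de_lfc = 1.5, de_rate = 0.5,
                       dp_weights = c(0.5, 0.9), dm_rate = 0.5,
                       pos_mu = 8, pos_theta = 4, mode_mu = c(3, 96),
                       mode_theta = 10) {
  n_tot <- sum(n_cells)
  grp <- rep(c("g1", "g2"), n_cells)
  depth <- rlnorm(n_tot, depth_meanlog, depth_sdlog)
  rel <- depth / median(depth)
  z <- scale(log(depth))[, 1L]
  p_drop <- if (dropout) plogis(-2 - z) else rep(0, n_tot)

  n_bg <- n_genes + n_mirna_null
  mu_g <- rlnorm(n_bg, mu_meanlog, mu_sdlog)
  theta_g <- rlnorm(n_bg, log(theta_shape), 0.1)
  bg <- matrix(0L, n_bg, n_tot)
  for (g in seq_len(n_bg)) {
    y <- rnbinom(n_tot, mu = mu_g[g] * rel, size = theta_g[g])
    keep <- rbinom(n_tot, 1L, 1 - p_drop)
    bg[g, ] <- y * keep
  }
  rownames(bg) <- c(sprintf("g%03d", seq_len(n_genes)),
                    if (n_mirna_null > 0L)
                      sprintf("mir-null-%d", seq_len(n_mirna_null)))

  spikes <- rep(names(n_spike), n_spike)
  sp <- matrix(0L, length(spikes), n_tot)
  sp_ids <- character(length(spikes))
  g1 <- grp == "g1"
  for (s in seq_along(spikes)) {
    cat_s <- spikes[s]
    sp_ids[s] <- sprintf("mir-%s-%d", tolower(cat_s), s)
    row <- integer(n_tot)
    # positive-count means scale with each cell's depth factor, like any
    # real transcript; detection probabilities are set directly
    if (cat_s == "DZ") {
      det <- rbinom(n_tot, 1L, ifelse(g1, dz_rates[1L], dz_rates[2L]))
      idx <- which(det == 1L)
      row[idx] <- .rnbinom_pos(length(idx), pos_mu * rel[idx], pos_theta)
    } else if (cat_s == "DE") {
      det <- rbinom(n_tot, 1L, de_rate)
      mu <- ifelse(g1, pos_mu, pos_mu * 2^de_lfc) * rel
      idx <- which(det == 1L)
      row[idx] <- .rnbinom_pos(length(idx), mu[idx], pos_theta)
    } else if (cat_s == "DP") {
      det <- rbinom(n_tot, 1L, de_rate)
      wlow <- ifelse(g1, dp_weights[1L], dp_weights[2L])
      idx <- which(det == 1L)
      low <- runif(length(idx)) < wlow[idx]
      row[idx[low]] <- .rnbinom_pos(sum(low), mode_mu[1L] * rel[idx[low]],
                                    mode_theta)
      row[idx[!low]] <- .rnbinom_pos(sum(!low), mode_mu[2L] * rel[idx[!low]],
                                     mode_theta)
    } else if (cat_s == "DM") {
      det <- rbinom(n_tot, 1L, dm_rate)
      idx <- which(det == 1L)
      low <- ifelse(g1[idx], runif(length(idx)) < 0.5, TRUE)
      row[idx[low]] <- .rnbinom_pos(sum(low), mode_mu[1L] * rel[idx[low]],
                                    mode_theta)
      row[idx[!low]] <- .rnbinom_pos(sum(!low), mode_mu[2L] * rel[idx[!low]],
                                     mode_theta)
    } else stop("unknown spike category: ", cat_s, call. = FALSE)
    sp[s, ] <- row
  }
  rownames(sp) <- sp_ids

  mat <- rbind(bg, sp)
  barcodes <- sprintf("CB%05d", seq_len(n_tot))
  colnames(mat) <- barcodes
  counts <- list(
    counts = as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix"),
    features = data.frame(
      feature_id = rownames(mat),
      feature_type = rep(c("coding", "miRNA_gene"),
                         c(n_genes, n_mirna_null + length(spikes))),
      stringsAsFactors = FALSE),
    barcodes = barcodes)
  truth <- data.frame(
    gene_id = c(rownames(bg), sp_ids),
    category = c(rep("null", n_bg), spikes), stringsAsFactors = FALSE)
  meta <- data.frame(barcode = barcodes, group = grp,
                     nCount = Matrix::colSums(counts$counts),
                     stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, truth = truth)
}

#' Write SAM lines to a file
#'
#' @param sam character vector of SAM lines (e.g. from
#'   [sim_alignments()]).
#' @param file output path.
#' @export
write_sam <- function(sam, file) {
  writeLines(sam, file)
  invisible(file)
}
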