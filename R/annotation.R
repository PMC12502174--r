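#' Reconcile a candidate transcript with existing annotation
#'
#' Implements the keep-longer rule used when a discovered transcribed region
#' matches an annotated transcript: if any annotated interval overlaps the
#' candidate, the longer of the candidate and the best-overlapping annotated
#' interval is kept; with no overlap the candidate is returned unchanged.
#'
#' @param candidate a one-row data.frame (or list) with `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open.
#' @param annotated a data.frame of annotated intervals with the same
#'   columns; may have zero rows.
#' @return a one-row data.frame with the reconciled interval.
#' @export
reconcile_with_annotation <- function(candidate, annotated) {
  cand <- as.data.frame(candidate, stringsAsFactors = FALSE)
  .check_interval(cand$chrom, cand$start, cand$end, cand$strand, "candidate")
  if (is.null(annotated) || nrow(annotated) == 0L)
    return(.interval_df(cand$chrom, cand$start, cand$end, cand$strand))
  if (any(annotated$chrom != cand$chrom) || any(annotated$strand != cand$strand))
    stop("annotated intervals must share the candidate's chrom and strand",
         call. = FALSE)
  .check_interval(annotated$chrom, annotated$start, annotated$end,
                  annotated$strand, "annotated")
  ov <- pmin(annotated$end, cand$end) - pmax(annotated$start, cand$start)
  hit <- which(ov > 0)
  if (length(hit) == 0L)
    return(.interval_df(cand$chrom, cand$start, cand$end, cand$strand))
  # best-overlapping annotated interval: max overlap, ties by length then order
  len <- annotated$end - annotated$start
  best <- hit[order(-ov[hit], -len[hit])][1L]
  if (len[best] > (cand$end - cand$start))
    .interval_df(cand$chrom, annotated$start[best], annotated$end[best],
                 cand$strand)
  else
    .interval_df(cand$chrom, cand$start, cand$end, cand$strand)
}

#' Refine a transcription start site using CAGE evidence
#'
#' Moves the 5' end of a candidate transcript to the highest-scoring CAGE
#' TSS within `window` bases of the current 5' end. Ties are broken toward
#' the position closest to the original 5' end. The 3' end never moves.
#'
#' @param candidate one-row data.frame with `chrom`, `start`, `end`, `strand`.
#' @param cage data.frame of CAGE tags with columns `chrom`, `position`
#'   (0-based), `strand`, `score`.
#' @param window search radius in bases around the candidate 5' end.
#' @return one-row data.frame with the refined interval.
#' @export
refine_tss <- function(candidate, cage, window = 500L) {
  cand <- as.data.frame(candidate, stringsAsFactors = FALSE)
  .check_interval(cand$chrom, cand$start, cand$end, cand$strand, "candidate")
  stopifnot(window > 0)
  fp <- .five_prime(cand$start, cand$end, cand$strand)
  if (!is.null(cage) && nrow(cage) > 0L) {
    if (any(cage$score < 0)) stop("CAGE scores must be non-negative", call. = FALSE)
    keep <- cage$chrom == cand$chrom & cage$strand == cand$strand &
      abs(cage$position - fp) <= window
    cg <- cage[keep, , drop = FALSE]
  } else cg <- NULL
  if (is.null(cg) || nrow(cg) == 0L)
    return(.interval_df(cand$chrom, cand$start, cand$end, cand$strand))
  best <- cg[order(-cg$score, abs(cg$position - fp), cg$position), ][1L, ]
  if (cand$strand == "+") {
    new_start <- as.integer(best$position); new_end <- cand$end
  } else {
    new_start <- cand$start; new_end <- as.integer(best$position) + 1L
  }
  if (new_start >= new_end)
    stop("TSS refinement would invert the interval", call. = FALSE)
  .interval_df(cand$chrom, new_start, new_end, cand$strand)
}

# Two-segment least-squares split of a numeric vector. Returns the split
# index j in 0..m (segment 1 = v[seq_len(j)]) minimizing total SSE; ties go
# to the smallest j.
.best_split <- function(v) {
  m <- length(v)
  cs <- c(0, cumsum(v)); css <- c(0, cumsum(v^2))
  j <- 0:m
  n1 <- j; n2 <- m - j
  s1 <- cs[j + 1L]; s2 <- cs[m + 1L] - s1
  q1 <- css[j + 1L]; q2 <- css[m + 1L] - q1
  sse1 <- q1 - ifelse(n1 > 0, s1^2 / n1, 0)
  sse2 <- q2 - ifelse(n2 > 0, s2^2 / n2, 0)
  cost <- sse1 + sse2
  j[which.min(cost)]
}

#' Extend a transcript 3' end by change-point analysis of coverage
#'
#' Scans up to `search_span` bases downstream of the current 3' end for the
#' position minimizing the two-segment squared-error cost of the
#' nascent-transcription signal. The split is accepted only if the mean
#' signal after the change point is at most `min_drop_fraction` times the
#' mean before it (each mean over up to `window` bases, truncated at the
#' coverage bounds); otherwise the end extends by the full `search_span`.
#' The 5' end never moves.
#'
#' @param candidate one-row data.frame with `chrom`, `start`, `end`, `strand`.
#' @param coverage a coverage track: list with `chrom`, `strand`, `start`
#'   (genomic origin of the vector, 0-based) and `values` (per-base,
#'   non-negative). See [sim_tracks()] and [read_bedgraph_track()].
#' @param search_span maximum extension in bases (default 10000).
#' @param min_drop_fraction acceptance gate: mean-after / mean-before must
#'   not exceed this (default 0.2).
#' @param window bases on each side of a split used for the gate means
#'   (default 500).
#' @return one-row data.frame with the extended interval.
#' @export
extend_end_changepoint <- function(candidate, coverage, search_span = 10000L,
                                   min_drop_fraction = 0.2, window = 500L) {
  cand <- as.data.frame(candidate, stringsAsFactors = FALSE)
  .check_interval(cand$chrom, cand$start, cand$end, cand$strand, "candidate")
  stopifnot(search_span > 0, min_drop_fraction > 0, window > 0)
  if (!identical(coverage$chrom, cand$chrom) ||
      !identical(coverage$strand, cand$strand))
    stop("coverage track chrom/strand do not match the candidate", call. = FALSE)
  if (any(coverage$values < 0)) stop("coverage must be non-negative", call. = FALSE)
  cov_start <- as.integer(coverage$start)
  cov_end <- cov_start + length(coverage$values)

  plus <- cand$strand == "+"
  end3 <- if (plus) cand$end else cand$start      # current 3' boundary
  # orient so that "downstream" is increasing index
  if (plus) {
    if (end3 >= cov_end) stop("coverage does not reach the 3' end", call. = FALSE)
    scan_hi <- min(end3 + search_span, cov_end)
    v <- coverage$values[(end3 - cov_start + 1L):(scan_hi - cov_start)]
    at <- function(j) end3 + j                      # genomic end for split j
    gate_lo <- cov_start; gate_hi <- cov_end
    gv <- coverage$values; gorig <- cov_start
  } else {
    if (end3 <= cov_start) stop("coverage does not reach the 3' end", call. = FALSE)
    scan_lo <- max(end3 - search_span, cov_start)
    v <- rev(coverage$values[(scan_lo - cov_start + 1L):(end3 - cov_start)])
    at <- function(j) end3 - j
    gv <- rev(coverage$values); gorig <- cov_start  # index i = cov_end - pos
  }
  if (length(v) < 1L) stop("coverage shorter than required span", call. = FALSE)

  j <- .best_split(v)
  cpt <- at(j)                                      # proposed genomic 3' end
  # gate means over up to `window` bases on each side, in oriented frame
  ori_pos <- function(p) if (plus) p - gorig else (gorig + length(gv)) - p
  k <- ori_pos(cpt)                                 # oriented index of split
  before <- gv[max(1L, k - window + 1L):k]
  after_hi <- min(length(gv), k + window)
  after <- if (after_hi >= k + 1L) gv[(k + 1L):after_hi] else numeric(0)
  mb <- if (length(before)) mean(before) else 0
  ma <- if (length(after)) mean(after) else 0
  accept <- ma <= min_drop_fraction * mb
  new3 <- if (accept) cpt else end3 + if (plus) search_span else -search_span
  if (plus) .interval_df(cand$chrom, cand$start, new3, cand$strand)
  else .interval_df(cand$chrom, new3, cand$end, cand$strand)
}

#' Summarize transcripts into a miRNA gene locus
#'
#' Merges candidate transcripts of one miRNA gene into a single locus
#' spanning the most distal TSS through the longest transcript end:
#' `[min(start), max(end))` on either strand (for minus-strand loci the most
#' distal TSS is the maximal end).
#'
#' @param transcripts data.frame of transcript intervals (same chrom/strand).
#' @param members data.frame of member pre-miRNAs with columns `name`,
#'   `chrom`, `start`, `end`, `strand`.
#' @return a locus: list with `gene_id` (NA until named), `chrom`, `start`,
#'   `end`, `strand`, `members`, `locus_class` (NA until classified),
#'   `host_gene_id`, `alt_transcripts`.
#' @export
summarize_locus <- function(transcripts, members) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    stop("no transcripts to summarize", call. = FALSE)
  .check_interval(transcripts$chrom, transcripts$start, transcripts$end,
                  transcripts$strand, "transcript")
  if (length(unique(transcripts$chrom)) != 1L ||
      length(unique(transcripts$strand)) != 1L)
    stop("transcripts must share one chrom and strand", call. = FALSE)
  for (i in seq_len(nrow(transcripts))) {
    if (!any(.overlaps(transcripts$start[i], transcripts$end[i],
                       members$start, members$end) &
             members$chrom == transcripts$chrom[i] &
             members$strand == transcripts$strand[i]))
      stop("transcript ", i, " overlaps no member pre-miRNA", call. = FALSE)
  }
  lo <- min(transcripts$start); hi <- max(transcripts$end)
  if (any(!(members$start >= lo & members$end <= hi)))
    stop("member pre-miRNA outside the merged locus span", call. = FALSE)
  list(gene_id = NA_character_, chrom = transcripts$chrom[1L],
       start = as.integer(lo), end = as.integer(hi),
       strand = transcripts$strand[1L], members = members,
       locus_class = NA_character_, host_gene_id = NA_character_,
       alt_transcripts = list())
}

#' Classify a miRNA gene locus as intragenic or intergenic
#'
#' A locus is intragenic iff at least one member pre-miRNA lies entirely
#' within a same-strand gene body; antisense overlap does not count. Ties
#' among candidate hosts are broken by the largest overlap with the locus,
#' then lexicographic gene id.
#'
#' @param locus a locus as returned by [summarize_locus()].
#' @param genes data.frame of gene bodies: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return the locus with `locus_class` and `host_gene_id` filled in.
#' @export
classify_locus <- function(locus, genes) {
  locus$locus_class <- "intergenic"
  locus$host_gene_id <- NA_character_
  if (!is.null(genes) && nrow(genes) > 0L) {
    m <- locus$members
    host <- logical(nrow(genes))
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != locus$chrom || genes$strand[g] != locus$strand) next
      host[g] <- any(.contained(m$start, m$end, genes$start[g], genes$end[g]))
    }
    if (any(host)) {
      cand <- genes[host, , drop = FALSE]
      ov <- pmin(cand$end, locus$end) - pmax(cand$start, locus$start)
      cand <- cand[order(-ov, cand$gene_id), , drop = FALSE]
      locus$locus_class <- "intragenic"
      locus$host_gene_id <- cand$gene_id[1L]
    }
  }
  locus
}

#' Build miRNA gene loci from pre-miRNA coordinates and evidence tracks
#'
#' Runs the full annotation pipeline: each pre-miRNA seeds a candidate
#' transcript; the 5' end is refined with CAGE TSS evidence
#' ([refine_tss()]); the 3' end is extended by change-point analysis of the
#' strand-matched coverage ([extend_end_changepoint()]); candidates are
#' reconciled with any known transcript annotation (keep-longer,
#' [reconcile_with_annotation()]); overlapping same-strand candidates are
#' merged by single linkage into clustered loci; and each locus is
#' classified against the gene models ([classify_locus()]). Locus gene ids
#' are the member pre-miRNA names joined with `~`.
#'
#' @param premirna data.frame of pre-miRNAs: `name`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @param cage CAGE tags as in [refine_tss()]; NULL to skip refinement.
#' @param tracks list of coverage tracks (each as in
#'   [extend_end_changepoint()]); the track matching each candidate's
#'   chrom/strand is used. NULL skips extension.
#' @param genes gene bodies for classification (see [classify_locus()]);
#'   NULL marks all loci intergenic.
#' @param known_transcripts optional data.frame of annotated transcript
#'   intervals used for the keep-longer reconciliation.
#' @param tss_window,search_span,min_drop_fraction,window tuning parameters
#'   passed through to the component operations.
#' @return list of loci (see [summarize_locus()]), each with `gene_id` set.
#' @export
build_mirna_loci <- function(premirna, cage = NULL, tracks = NULL,
                             genes = NULL, known_transcripts = NULL,
                             tss_window = 500L, search_span = 10000L,
                             min_drop_fraction = 0.2, window = 500L) {
  .check_interval(premirna$chrom, premirna$start, premirna$end,
                  premirna$strand, "pre-miRNA")
  n <- nrow(premirna)
  cands <- premirna[, c("chrom", "start", "end", "strand")]
  for (i in seq_len(n)) {
    ci <- cands[i, , drop = FALSE]
    if (!is.null(cage)) ci <- refine_tss(ci, cage, tss_window)
    if (!is.null(tracks)) {
      trk <- NULL
      for (t in tracks)
        if (identical(t$chrom, ci$chrom) && identical(t$strand, ci$strand)) trk <- t
      if (!is.null(trk))
        ci <- extend_end_changepoint(ci, trk, search_span, min_drop_fraction,
                                     window)
    }
    if (!is.null(known_transcripts)) {
      kt <- known_transcripts[known_transcripts$chrom == ci$chrom &
                                known_transcripts$strand == ci$strand, ,
                              drop = FALSE]
      ci <- reconcile_with_annotation(ci, kt)
    }
    cands[i, ] <- ci
  }
  grp <- .overlap_groups(cands)
  loci <- vector("list", length(unique(grp)))
  for (k in seq_along(unique(grp))) {
    idx <- which(grp == unique(grp)[k])
    loc <- summarize_locus(cands[idx, , drop = FALSE],
                           premirna[idx, , drop = FALSE])
    loc$gene_id <- paste(sort(premirna$name[idx]), collapse = "~")
    loc <- classify_locus(loc, genes)
    loci[[k]] <- loc
  }
  # deterministic order: chrom, start
  ord <- order(vapply(loci, `[[`, "", "chrom"),
               vapply(loci, `[[`, 0L, "start"))
  loci[ord]
}
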