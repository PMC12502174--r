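# Internal interval arithmetic. All coordinates are 0-based half-open
# [start, end); strand is "+" or "-". Loci and gene models are plain
# data.frames so the rest of the package stays convention-safe; conversion
# to GRanges (1-based) happens only at the rtracklayer I/O boundary.

.check_interval <- function(chrom, start, end, strand, what = "interval") {
  if (any(!strand %in% c("+", "-")))
    stop(what, ": strand must be '+' or '-'", call. = FALSE)
  if (any(start < 0) || any(start >= end))
    stop(what, ": require 0 <= start < end", call. = FALSE)
  invisible(TRUE)
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.contained <- function(s1, e1, s2, e2) s2 <= s1 & e1 <= e2

# 5' end position of an interval (the TSS side)
.five_prime <- function(start, end, strand) ifelse(strand == "+", start, end - 1L)

#' @noRd
.interval_df <- function(chrom, start, end, strand) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

# Single-linkage grouping of same-chrom/strand intervals by overlap.
# Returns an integer group id per row.
.overlap_groups <- function(df) {
  n <- nrow(df)
  grp <- integer(n)
  next_id <- 0L
  key <- paste(df$chrom, df$strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- idx[order(df$start[idx])]
    cur_end <- -Inf
    for (i in o) {
      if (df$start[i] < cur_end) {
        grp[i] <- next_id
        cur_end <- max(cur_end, df$end[i])
      } else {
        next_id <- next_id + 1L
        grp[i] <- next_id
        cur_end <- df$end[i]
      }
    }
  }
  grp
}
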