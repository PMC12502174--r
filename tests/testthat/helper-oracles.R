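# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check: combinatorics are
# written out with choose(), the step-up adjustment by hand, and the
# chi-square survival function as its even-df closed form.

# two-sided exact conditional p for a 2x2 table by full enumeration:
# k1 of n1 vs k2 of n2 detected; sums P(table) over all tables with the
# same margins whose probability does not exceed the observed one.
enum_exact_p <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  support <- max(0, K - n2):min(K, n1)
  denom <- choose(n1 + n2, K)
  probs <- choose(n1, support) * choose(n2, K - support) / denom
  obs <- probs[support == k1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# upper-tail hypergeometric by enumeration: P(overlap >= k) drawing nd
# genes from a universe of N containing m targets.
enum_hyper_tail <- function(k, m, N, nd) {
  kk <- k:min(m, nd)
  sum(choose(m, kk) * choose(N - m, nd - kk)) / choose(N, nd)
}

# step-up BH written independently of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# chi-square survival function for even df = 2k:
# P(X > x) = exp(-x/2) * sum_{j=0}^{k-1} (x/2)^j / j!
chisq_sf_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# locus constructor for tests
make_locus <- function(gene_id, chrom, start, end, strand,
                       members = NULL, alt = list()) {
  if (is.null(members))
    members <- data.frame(name = gene_id, chrom = chrom,
                          start = start, end = end, strand = strand,
                          stringsAsFactors = FALSE)
  list(gene_id = gene_id, chrom = chrom, start = as.integer(start),
       end = as.integer(end), strand = strand, members = members,
       locus_class = NA_character_, host_gene_id = NA_character_,
       alt_transcripts = alt)
}

# flat coverage track over [0, len) with optional step down at `step_at`
make_track <- function(chrom, strand, len, high = 10, low = 0,
                       step_at = NULL, noise_sd = 0) {
  v <- rep(high, len)
  if (!is.null(step_at)) v[(step_at + 1):len] <- low
  if (noise_sd > 0) v <- pmax(v + rnorm(len, 0, noise_sd), 0)
  list(chrom = chrom, strand = strand, start = 0L, values = v)
}
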