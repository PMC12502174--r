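#' Combine p-values across cell types with Fisher's method
#'
#' Computes the Fisher combined-probability statistic `-2 * sum(log(p))`
#' and refers it to a chi-square distribution with `2k` degrees of freedom
#' (the `sumlog` construction). P-values below `floor` are clamped to
#' `floor` so a single numerical zero cannot dominate.
#'
#' @param p numeric vector of at least two p-values in (0, 1].
#' @param floor clamp for tiny p-values (default 1e-300); set to 0 to
#'   disable clamping, in which case p = 0 is an error.
#' @return list with `statistic`, `df`, `combined_p`.
#' @export
fisher_combine <- function(p, floor = 1e-300) {
  if (length(p) < 2L) stop("need at least two p-values", call. = FALSE)
  if (any(!is.finite(p)) || any(p > 1))
    stop("p-values must be finite and <= 1", call. = FALSE)
  if (floor > 0) p <- pmax(p, floor)
  if (any(p <= 0)) stop("p-values must be positive (or clamped)", call. = FALSE)
  stat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = stat, df = df,
       combined_p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Log2 fold change in detection rate with a pseudorate
#'
#' `log2((rate_a + eps) / (rate_b + eps))`; the pseudorate keeps
#' zero-detection genes finite.
#'
#' @param rate_a,rate_b detection rates in \[0, 1\].
#' @param eps pseudorate (> 0); the convention used by [run_dd()] is
#'   1 / (smaller group size + 1).
#' @return log2 ratio (vectorized).
#' @export
detection_log2fc <- function(rate_a, rate_b, eps = 0.01) {
  stopifnot(eps > 0)
  log2((rate_a + eps) / (rate_b + eps))
}

#' Rank concordantly regulated miRNA genes across cell types
#'
#' Combines each gene's per-cell-type p-values with Fisher's method (cell
#' types where the gene was not tested contribute p = 1) and retains genes
#' with combined p below `combined_alpha` whose absolute detection-rate log2
#' fold change exceeds `fc_cut` in at least `min_celltypes` cell types.
#' Direction concordance is not required — only the magnitude cutoff counts.
#' The result is sorted by combined p, ties broken by more cell types
#' passing the fold-change cut, then gene id, giving a total order.
#'
#' @param dd_list named list of [run_dd()] result data.frames, one per cell
#'   type.
#' @param p_col column holding the per-cell-type p-value to combine
#'   (default `"p_dz"`, the detection family; use `"p_expr"` for the
#'   expression family).
#' @param fc_col column holding the fold change screened by `fc_cut`.
#' @param combined_alpha,fc_cut,min_celltypes filtering parameters
#'   (defaults 0.05, 0.5, 2).
#' @param floor passed to [fisher_combine()].
#' @return data.frame: `gene_id`, `fisher_statistic`, `df`, `combined_p`,
#'   `combined_p_adj` (BH across all genes, before filtering),
#'   `n_pass_fc`, plus per-cell-type `p_<ct>` and `fc_<ct>` columns.
#' @export
rank_concordant <- function(dd_list, p_col = "p_dz",
                            fc_col = "log2_detect_fc", combined_alpha = 0.05,
                            fc_cut = 0.5, min_celltypes = 2L,
                            floor = 1e-300) {
  if (length(dd_list) == 0L) return(.empty_ranked(character(0)))
  if (is.null(names(dd_list)))
    names(dd_list) <- paste0("celltype", seq_along(dd_list))
  cts <- names(dd_list)
  genes <- sort(unique(unlist(lapply(dd_list, `[[`, "gene_id"))))
  if (length(genes) == 0L) return(.empty_ranked(cts))
  pm <- matrix(1, length(genes), length(cts),
               dimnames = list(genes, cts))
  fm <- matrix(0, length(genes), length(cts),
               dimnames = list(genes, cts))
  for (ct in cts) {
    d <- dd_list[[ct]]
    pm[d$gene_id, ct] <- d[[p_col]]
    fm[d$gene_id, ct] <- d[[fc_col]]
  }
  comb <- t(apply(pm, 1L, function(p) {
    if (length(p) == 1L) {
      # degenerate single-cell-type case: -2 ln p ~ chi-square(2), whose
      # survival at -2 ln p is p itself
      pc <- max(p, floor)
      return(c(-2 * log(pc), 2, pc))
    }
    f <- fisher_combine(p, floor = floor)
    c(f$statistic, f$df, f$combined_p)
  }))
  n_pass <- rowSums(abs(fm) > fc_cut)
  out <- data.frame(gene_id = genes, fisher_statistic = comb[, 1L],
                    df = as.integer(comb[, 2L]), combined_p = comb[, 3L],
                    combined_p_adj = adjust_bh(comb[, 3L]),
                    n_pass_fc = as.integer(n_pass),
                    stringsAsFactors = FALSE)
  colnames(pm) <- paste0("p_", cts)
  colnames(fm) <- paste0("fc_", cts)
  out <- cbind(out, as.data.frame(pm), as.data.frame(fm))
  rownames(out) <- NULL
  keep <- out$combined_p < combined_alpha & out$n_pass_fc >= min_celltypes
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$combined_p, -out$n_pass_fc, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_ranked <- function(cts) {
  out <- data.frame(gene_id = character(0), fisher_statistic = numeric(0),
                    df = integer(0), combined_p = numeric(0),
                    combined_p_adj = numeric(0), n_pass_fc = integer(0),
                    stringsAsFactors = FALSE)
  for (ct in cts) out[[paste0("p_", ct)]] <- numeric(0)
  for (ct in cts) out[[paste0("fc_", ct)]] <- numeric(0)
  out
}
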