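#' miRNA target-set over-representation on a differential gene list
#'
#' For each miRNA, counts the overlap between the differential gene list
#' (nominal p below `nominal_alpha`) and the miRNA's target set, both
#' restricted to the tested universe, and computes the upper-tail
#' hypergeometric p-value (one-sided over-representation). P-values are
#' BH-adjusted across miRNAs and flagged significant at adjusted
#' p < `fdr`.
#'
#' @param de_genes data.frame with `gene_id` and `p` (nominal p-values), or
#'   a character vector of already-selected genes.
#' @param universe character vector of all tested gene ids.
#' @param targets data.frame with `mirna_id`, `gene_id` (TargetScan-style
#'   interaction table).
#' @param nominal_alpha nominal p cutoff selecting the DE list
#'   (default 0.05).
#' @param fdr adjusted-p threshold for the significance flag (default 0.1).
#' @return data.frame sorted by adjusted p then decreasing overlap:
#'   `mirna_id`, `n_targets` (in universe), `n_de`, `overlap`, `p_value`,
#'   `adj_p`, `significant`.
#' @export
enrich_targets <- function(de_genes, universe, targets,
                           nominal_alpha = 0.05, fdr = 0.1) {
  de <- if (is.data.frame(de_genes))
    de_genes$gene_id[de_genes$p < nominal_alpha] else as.character(de_genes)
  if (!all(de %in% universe))
    stop("differential gene list must be a subset of the universe",
         call. = FALSE)
  de <- unique(de)
  universe <- unique(universe)
  N <- length(universe); nd <- length(de)
  mirnas <- sort(unique(targets$mirna_id))
  res <- lapply(mirnas, function(mir) {
    set <- intersect(unique(targets$gene_id[targets$mirna_id == mir]),
                     universe)
    k <- length(intersect(de, set))
    p <- if (nd == 0L || length(set) == 0L) 1 else
      phyper(k - 1L, length(set), N - length(set), nd, lower.tail = FALSE)
    data.frame(mirna_id = mir, n_targets = length(set), n_de = nd,
               overlap = k, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- adjust_bh(out$p_value)
  out$significant <- out$adj_p < fdr
  out <- out[order(out$adj_p, -out$overlap, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Calibrate a Ct table against the plate calibration control
#'
#' Per sample, subtracts that sample's calibrator offset (its calibrator Ct
#' minus the mean calibrator Ct across samples) from every assay Ct, then
#' censors values above the detection cutoff. Samples lacking a calibrator
#' row are excluded with a warning.
#'
#' @param ct_table data.frame with `sample_id`, `group`, `assay_id`,
#'   `assay_class` (one of `target`, `reference`, `spike`, `calibrator`)
#'   and `ct` (NA for undetected).
#' @param ct_cutoff detection limit; corrected Ct above it becomes NA
#'   (default 35).
#' @return the corrected Ct table (excluded samples dropped).
#' @export
calibrate_ct <- function(ct_table, ct_cutoff = 35) {
  stopifnot(all(ct_table$ct[!is.na(ct_table$ct)] > 0))
  cal <- ct_table[ct_table$assay_class == "calibrator" & !is.na(ct_table$ct), ]
  cal_mean <- tapply(cal$ct, cal$sample_id, mean)
  have <- unique(ct_table$sample_id) %in% names(cal_mean)
  if (!all(have)) {
    miss <- unique(ct_table$sample_id)[!have]
    warning("samples without calibrator excluded: ",
            paste(miss, collapse = ", "))
    ct_table <- ct_table[ct_table$sample_id %in% names(cal_mean), ,
                         drop = FALSE]
  }
  shift <- cal_mean[as.character(ct_table$sample_id)] - mean(cal_mean)
  ct_table$ct <- ct_table$ct - as.numeric(shift)
  ct_table$ct[!is.na(ct_table$ct) & ct_table$ct > ct_cutoff] <- NA_real_
  ct_table
}

#' Relative expression by the 2^(-Avg(DeltaCt)) method
#'
#' Per sample, DeltaCt of each target assay is its Ct minus the mean Ct of
#' the detected reference assays; relative expression is 2^(-DeltaCt).
#' Undetected targets, and all targets of samples with no detected
#' reference, yield NA.
#'
#' @param ct_table a (calibrated) Ct table, see [calibrate_ct()].
#' @param reference_assays assay ids to normalize against; default: all
#'   assays with `assay_class == "reference"`.
#' @return data.frame: `sample_id`, `group`, `assay_id`, `delta_ct`,
#'   `rel_expr`.
#' @export
relative_expression <- function(ct_table, reference_assays = NULL) {
  if (is.null(reference_assays))
    reference_assays <- unique(ct_table$assay_id[
      ct_table$assay_class == "reference"])
  tgt <- ct_table[ct_table$assay_class == "target", , drop = FALSE]
  out <- list()
  for (s in unique(tgt$sample_id)) {
    refs <- ct_table$ct[ct_table$sample_id == s &
                          ct_table$assay_id %in% reference_assays]
    refs <- refs[!is.na(refs)]
    ref_mean <- if (length(refs)) mean(refs) else {
      warning("sample ", s, " has no detected reference assay")
      NA_real_
    }
    t <- tgt[tgt$sample_id == s, , drop = FALSE]
    dct <- t$ct - ref_mean
    out[[length(out) + 1L]] <- data.frame(
      sample_id = s, group = t$group, assay_id = t$assay_id,
      delta_ct = dct, rel_expr = 2^(-dct), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold regulation between two groups of relative-expression values
#'
#' Fold change is the ratio of group means of relative expression; fold
#' regulation reports it as FC when FC >= 1 and -1/FC otherwise. The
#' p-value comes from an unpaired two-tailed t-test on the DeltaCt scale
#' (DeltaCt = -log2(relative expression)); it is NA when either group has
#' fewer than two detected samples, and 1 when all values are identical.
#'
#' @param group_a,group_b numeric vectors of relative-expression values
#'   (NA = undetected, dropped).
#' @return list with `fold_change`, `fold_regulation`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
fold_regulation <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  fc <- mean(a) / mean(b)
  fr <- if (is.na(fc)) NA_real_ else if (fc >= 1) fc else -1 / fc
  p <- NA_real_
  if (length(a) >= 2L && length(b) >= 2L) {
    da <- -log2(a); db <- -log2(b)
    if (stats::sd(c(da, db)) < 1e-12) p <- 1
    else p <- tryCatch(t.test(da, db)$p.value, error = function(e) NA_real_)
  }
  list(fold_change = fc, fold_regulation = fr, p_value = p,
       n_a = length(a), n_b = length(b))
}

#' QC check of spike-in control assays
#'
#' Flags each spike-in control (assay_class `spike`) per sample as passing
#' when its Ct lies inside the expected range. Spike-ins are QC only — they
#' never enter normalization.
#'
#' @param ct_table Ct table, see [calibrate_ct()].
#' @param ct_range acceptable Ct range (default c(15, 30)).
#' @return data.frame: `sample_id`, `assay_id`, `ct`, `pass`.
#' @export
qc_spikes <- function(ct_table, ct_range = c(15, 30)) {
  sp <- ct_table[ct_table$assay_class == "spike", , drop = FALSE]
  data.frame(sample_id = sp$sample_id, assay_id = sp$assay_id, ct = sp$ct,
             pass = !is.na(sp$ct) & sp$ct >= ct_range[1L] &
               sp$ct <= ct_range[2L],
             stringsAsFactors = FALSE, row.names = NULL)
}
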