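# Permutation KS with the label-shuffle stream seeded from the session RNG,
# so set.seed() upstream makes results reproducible.
.perm_ks <- function(x1, x2, n_perm) {
  .perm_ks_cpp(as.numeric(x1), as.numeric(x2), as.integer(n_perm),
               sample.int(2147483647L, 1L))
}

# Differential-distribution testing between two condition groups, in two
# families: detection rate (DZ) and expression level among expressing cells
# (DE / DP / DM). Deterministic re-implementation of the four-category
# contract: an exact conditional 2x2 test for detection, a permutation
# Kolmogorov-Smirnov test for expression, and BIC-selected 1- vs 2-component
# Gaussian mixtures for category classification.

#' Exact conditional test for a difference in detection rate (DZ)
#'
#' Two-sided exact conditional test on the 2x2 table
#' (detected/undetected x group), conditioning on both margins: the p-value
#' sums hypergeometric probabilities of all tables no more likely than the
#' observed one (the minimum-likelihood rule, as in [stats::fisher.test()]).
#' An opt-in adjusted variant fits a logistic regression of detection on
#' group plus the per-cell detection rate and reports the two-sided Wald
#' p-value of the group coefficient.
#'
#' @param x1,x2 per-cell counts (or detection indicators) for the gene in
#'   group 1 and group 2.
#' @param adjusted use the detection-rate-adjusted logistic variant.
#' @param cdr1,cdr2 per-cell detection rates (fraction of genes detected in
#'   each cell), required when `adjusted = TRUE`.
#' @return list with `p_value`, `rate_g1`, `rate_g2`.
#' @export
test_dz <- function(x1, x2, adjusted = FALSE, cdr1 = NULL, cdr2 = NULL) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty", call. = FALSE)
  k1 <- sum(x1 > 0); k2 <- sum(x2 > 0)
  rates <- c(rate_g1 = k1 / n1, rate_g2 = k2 / n2)
  if (adjusted) {
    if (is.null(cdr1) || is.null(cdr2))
      stop("adjusted test needs per-cell detection rates", call. = FALSE)
    det <- c(x1 > 0, x2 > 0)
    grp <- factor(rep(c("g1", "g2"), c(n1, n2)))
    cdr <- c(cdr1, cdr2)
    fit <- suppressWarnings(glm(det ~ grp + cdr, family = binomial()))
    sm <- summary(fit)$coefficients
    p <- if ("grpg2" %in% rownames(sm)) sm["grpg2", 4L] else 1
    return(c(list(p_value = unname(p)), as.list(rates)))
  }
  K <- k1 + k2
  if (K == 0L || K == n1 + n2)
    return(c(list(p_value = 1), as.list(rates)))
  support <- max(0L, K - n2):min(K, n1)
  pr <- dhyper(support, n1, n2, K)
  obs <- pr[match(k1, support)]
  p <- min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  c(list(p_value = p), as.list(rates))
}

#' Permutation KS test and mixture classification of expression (DE/DP/DM)
#'
#' Compares nonzero normalized expression between groups with a permutation
#' test of the two-sample Kolmogorov-Smirnov statistic (group labels
#' shuffled; p = (1 + exceedances) / (1 + permutations)). When the
#' permutation p-value falls at or below `classify_alpha`, the distributions
#' are classified by fitting 1- vs 2-component Gaussian mixtures per group,
#' chosen by BIC: both unimodal is a mean shift (DE); both bimodal with
#' matched component means but different weights is a proportion shift (DP);
#' differing modality is DM. A fitted 2-component solution is treated as
#' bimodal only when its BIC beats the 1-component fit by at least
#' `bic_margin`, the component means are at least `min_sep` apart and both
#' weights exceed `min_weight` (guards against spurious splits of one
#' skewed mode; a 20-point BIC margin is decisive evidence on the
#' Kass-Raftery scale).
#'
#' @param x1,x2 nonzero normalized (log2-scale) expression values per group.
#' @param n_perm number of label permutations (default 1000).
#' @param min_nonzero minimum expressing cells per group; below it the gene
#'   is returned as NS with p = 1 (default 3).
#' @param classify_alpha working level at which classification is attempted.
#' @param mode_tol maximum difference (log2 units) for two component means
#'   to count as the same mode across groups (default 1).
#' @param min_sep,min_weight,bic_margin bimodality guards (defaults 2,
#'   0.05 and 20).
#' @return list with `category` (`DE`, `DP`, `DM` or `NS`), `p_value`, and
#'   `statistic` (observed KS D).
#' @export
test_expr_category <- function(x1, x2, n_perm = 1000L, min_nonzero = 3L,
                               classify_alpha = 0.05, mode_tol = 1,
                               min_sep = 2, min_weight = 0.05,
                               bic_margin = 20) {
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    stop("expression values must be finite", call. = FALSE)
  if (length(x1) < min_nonzero || length(x2) < min_nonzero)
    return(list(category = "NS", p_value = 1, statistic = NA_real_))
  ks <- .perm_ks(as.numeric(x1), as.numeric(x2), n_perm)
  if (ks$p_value > classify_alpha)
    return(list(category = "NS", p_value = ks$p_value,
                statistic = ks$statistic))
  list(category = classify_modes(x1, x2, mode_tol = mode_tol,
                                 min_sep = min_sep, min_weight = min_weight,
                                 bic_margin = bic_margin),
       p_value = ks$p_value, statistic = ks$statistic)
}

#' Classify two expression distributions into DE / DP / DM
#'
#' Both groups unimodal is a mean shift (DE); differing modality is DM.
#' When both groups are bimodal, whether the modes are shared is decided by
#' component occupancy: the group whose fitted modes are farther apart
#' anchors the reference components (a scarce component's mean is biased
#' when estimated from the other group alone), every cell of both groups is
#' assigned to the nearest reference mode, and if both groups occupy both
#' modes (minority share at least `min_share`) only the weights differ
#' (DP); a mode effectively private to one group is DM. `mode_tol` is kept
#' for the degenerate case where the reference modes collapse within it.
#'
#' @inheritParams test_expr_category
#' @param min_share minimum within-group share of a pooled component for it
#'   to count as present in that group (default 0.05).
#' @return one of `"DE"`, `"DP"`, `"DM"`.
#' @export
classify_modes <- function(x1, x2, mode_tol = 1, min_sep = 2,
                           min_weight = 0.05, bic_margin = 20,
                           min_share = 0.05) {
  f1 <- .fit_modes(x1, min_sep, min_weight, bic_margin)
  f2 <- .fit_modes(x2, min_sep, min_weight, bic_margin)
  if (f1$G == 1L && f2$G == 1L) return("DE")
  if (f1$G == 2L && f2$G == 2L) {
    ref <- if (diff(f1$means) >= diff(f2$means)) f1 else f2
    if (diff(ref$means) <= mode_tol)
      return("DP")                       # modes indistinguishable: weights only
    cl <- c(x1, x2)
    cl <- 1L + (abs(cl - ref$means[2L]) < abs(cl - ref$means[1L]))
    g <- rep(1:2, c(length(x1), length(x2)))
    share <- prop.table(table(factor(g, 1:2), factor(cl, 1:2)), 1L)
    if (all(share >= min_share)) return("DP")
    return("DM")
  }
  "DM"
}

# BIC-selected 1- vs 2-component Gaussian mixture for one group; collapses
# weakly supported, unseparated or degenerate 2-component fits back to
# unimodal.
.fit_modes <- function(x, min_sep, min_weight, bic_margin = 20) {
  if (length(x) < 5L || stats::sd(x) < 1e-8)
    return(list(G = 1L, means = mean(x), weights = 1))
  fit <- tryCatch(
    suppressWarnings(Mclust(x, G = 1:2, modelNames = c("E", "V"),
                            verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit) || fit$G == 1L)
    return(list(G = 1L, means = mean(x), weights = 1))
  bics <- suppressWarnings(apply(fit$BIC, 1L, max, na.rm = TRUE))
  if (length(bics) < 2L || !all(is.finite(bics)) ||
      bics[2L] - bics[1L] < bic_margin)
    return(list(G = 1L, means = mean(x), weights = 1))
  mu <- as.numeric(fit$parameters$mean)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  mu <- mu[o]; w <- w[o]
  if (diff(mu) < min_sep || min(w) < min_weight)
    return(list(G = 1L, means = mean(x), weights = 1))
  list(G = 2L, means = mu, weights = w)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (via [stats::p.adjust()]) with input
#' validation; order is preserved and output never falls below input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Differential-distribution analysis of a count matrix
#'
#' Runs the full per-gene pipeline between two groups of cells:
#' normalization ([vst_normalize()] by default), the exact detection-rate
#' test ([test_dz()]) on raw counts, the permutation KS expression test on
#' nonzero normalized values, BH adjustment within each family separately
#' (detection family; expression family), mixture classification of genes
#' whose expression family is significant, and the detection-rate log2 fold
#' change ([detection_log2fc()], pseudorate 1/(smaller group size + 1)).
#'
#' The final `category` is `DZ` when only the detection family is
#' significant at `alpha` (or when both are and the detection adjusted p is
#' no larger), the mixture class (`DE`/`DP`/`DM`) when the expression family
#' drives the call, and `NS` otherwise.
#'
#' @param counts cell count matrix (list form, see [read_matrix_dir()]) or a
#'   features x cells count matrix.
#' @param groups factor (or vector) of length ncol with exactly two levels,
#'   aligned to the matrix columns.
#' @param alpha significance level on BH-adjusted p-values (default 0.05).
#' @param normalization `"vst"` (default), `"depth"`, or `"none"`
#'   (log2(x+1)).
#' @param test_features optional character vector restricting which features
#'   are tested (all features are still used for normalization).
#' @param n_perm,min_nonzero,mode_tol,min_sep,min_weight,bic_margin passed
#'   to [test_expr_category()].
#' @param adjusted_dz use the detection-rate-adjusted logistic DZ variant.
#' @return data.frame with one row per tested gene: `gene_id`, `category`,
#'   `p_value`, `adj_p` (driving family), `p_dz`, `adj_p_dz`, `p_expr`,
#'   `adj_p_expr`, `rate_g1`, `rate_g2`, `log2_detect_fc`, `mean_g1`,
#'   `mean_g2`.
#' @export
run_dd <- function(counts, groups, alpha = 0.05,
                   normalization = c("vst", "depth", "none"),
                   test_features = NULL, n_perm = 1000L, min_nonzero = 3L,
                   mode_tol = 1, min_sep = 2, min_weight = 0.05,
                   bic_margin = 20, adjusted_dz = FALSE) {
  normalization <- match.arg(normalization)
  m <- if (is.list(counts) && !is.null(counts$counts)) counts$counts else counts
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(m))
    stop("groups must align with matrix columns", call. = FALSE)
  g1 <- groups == levels(groups)[1L]
  g2 <- !g1
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty", call. = FALSE)

  values <- switch(normalization,
                   vst = vst_normalize(m)$values,
                   depth = depth_normalize(m),
                   none = log2(m + 1))
  genes <- if (is.null(test_features)) rownames(m)
           else intersect(test_features, rownames(m))
  cdr <- colMeans(m > 0)
  eps <- 1 / (min(sum(g1), sum(g2)) + 1)

  n <- length(genes)
  p_dz <- p_expr <- rate1 <- rate2 <- mean1 <- mean2 <- numeric(n)
  expr_nz <- vector("list", n)
  for (i in seq_len(n)) {
    y <- m[genes[i], ]
    dz <- test_dz(y[g1], y[g2], adjusted = adjusted_dz,
                  cdr1 = if (adjusted_dz) cdr[g1] else NULL,
                  cdr2 = if (adjusted_dz) cdr[g2] else NULL)
    p_dz[i] <- dz$p_value; rate1[i] <- dz$rate_g1; rate2[i] <- dz$rate_g2
    v <- values[genes[i], ]
    nz1 <- v[g1 & y > 0]; nz2 <- v[g2 & y > 0]
    mean1[i] <- if (length(nz1)) mean(nz1) else NA_real_
    mean2[i] <- if (length(nz2)) mean(nz2) else NA_real_
    if (length(nz1) >= min_nonzero && length(nz2) >= min_nonzero) {
      ks <- .perm_ks(nz1, nz2, n_perm)
      p_expr[i] <- ks$p_value
      expr_nz[[i]] <- list(nz1, nz2)
    } else {
      p_expr[i] <- 1
    }
  }
  adj_dz <- adjust_bh(p_dz)
  adj_expr <- adjust_bh(p_expr)

  category <- rep("NS", n)
  for (i in seq_len(n)) {
    sig_dz <- adj_dz[i] < alpha
    sig_expr <- adj_expr[i] < alpha
    if (sig_dz && (!sig_expr || adj_dz[i] <= adj_expr[i])) {
      category[i] <- "DZ"
    } else if (sig_expr) {
      category[i] <- classify_modes(expr_nz[[i]][[1L]], expr_nz[[i]][[2L]],
                                    mode_tol = mode_tol, min_sep = min_sep,
                                    min_weight = min_weight,
                                    bic_margin = bic_margin)
    }
  }
  driving_dz <- category == "DZ" | (category == "NS" & adj_dz <= adj_expr)
  data.frame(gene_id = genes, category = category,
             p_value = ifelse(driving_dz, p_dz, p_expr),
             adj_p = ifelse(driving_dz, adj_dz, adj_expr),
             p_dz = p_dz, adj_p_dz = adj_dz,
             p_expr = p_expr, adj_p_expr = adj_expr,
             rate_g1 = rate1, rate_g2 = rate2,
             log2_detect_fc = detection_log2fc(rate1, rate2, eps),
             mean_g1 = mean1, mean_g2 = mean2,
             stringsAsFactors = FALSE)
}
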