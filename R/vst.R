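#' Variance-stabilizing normalization of UMI counts
#'
#' Fits, per gene, a negative-binomial regression of counts on
#' log10(total counts per cell), regularizes the three parameters
#' (intercept, depth coefficient, dispersion) by kernel smoothing over genes
#' ordered by geometric-mean expression — borrowing information across genes
#' of similar abundance — and outputs corrected counts: each observation is
#' mapped to the expected count at the median cell depth plus its Pearson
#' residual times the standard deviation expected there, clamped at zero,
#' then log2(x + 1) transformed.
#'
#' With equal depths in all cells the correction is the identity, so
#' constant genes come back as `log2(c + 1)` exactly. All-zero genes get a
#' degenerate zero model and an all-zero row.
#'
#' @param counts a cell count matrix (list with `counts`, see
#'   [read_matrix_dir()]) or a features x cells matrix of non-negative
#'   integer counts.
#' @param bw_scale multiplier on the Silverman bandwidth used for parameter
#'   smoothing (default 1.5).
#' @return list with `values` (genes x cells, log2 scale, >= 0),
#'   `residuals` (Pearson residuals under the regularized model),
#'   `model` (per-gene data.frame: `gene_id`, `intercept`, `depth_coef`,
#'   `theta`), and `cell_depth`.
#' @export
vst_normalize <- function(counts, bw_scale = 1.5) {
  m <- if (is.list(counts) && !is.null(counts$counts)) counts$counts else counts
  m <- as(m, "CsparseMatrix")
  if (ncol(m) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (any(m@x < 0)) stop("counts must be non-negative", call. = FALSE)
  depth <- Matrix::colSums(m)
  ld <- log10(pmax(depth, 1))
  n_genes <- nrow(m)
  gene_ids <- rownames(m)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))

  b0 <- b1 <- lth <- rep(NA_real_, n_genes)
  dense <- as.matrix(m)
  tot <- rowSums(dense)
  expressed <- tot > 0
  const_depth <- stats::sd(ld) < 1e-10
  for (g in which(expressed)) {
    y <- dense[g, ]
    if (const_depth || length(unique(y)) == 1L) {
      b0[g] <- log(mean(y)); b1[g] <- 0
      mu <- rep(mean(y), length(y))
    } else {
      fit <- tryCatch(glm(y ~ ld, family = poisson()),
                      error = function(e) NULL, warning = function(w)
                        suppressWarnings(glm(y ~ ld, family = poisson())))
      if (is.null(fit) || !fit$converged || any(!is.finite(coef(fit)))) {
        b0[g] <- log(mean(y)); b1[g] <- 0
        mu <- rep(mean(y), length(y))
      } else {
        b0[g] <- coef(fit)[1L]; b1[g] <- coef(fit)[2L]
        mu <- fitted(fit)
      }
    }
    th <- tryCatch(suppressWarnings(as.numeric(MASS::theta.ml(y, mu,
                                                              limit = 25))),
                   error = function(e) NA_real_)
    if (!is.finite(th) || th <= 0) {
      v <- var(y); mb <- mean(y)
      th <- if (is.finite(v) && v > mb) mb^2 / (v - mb) else 1e6
    }
    lth[g] <- log10(min(max(th, 1e-4), 1e6))
  }

  # regularize across genes ordered by geometric-mean expression
  gm <- log10(exp(rowMeans(log1p(dense))) )
  idx <- which(expressed)
  if (length(idx) >= 3L && stats::sd(gm[idx]) > 1e-10) {
    bw <- bw_scale * bw.nrd0(gm[idx])
    smooth_par <- function(p) {
      ks <- ksmooth(gm[idx], p[idx], kernel = "normal", bandwidth = bw,
                    x.points = gm[idx])
      out <- p
      # ksmooth returns values ordered by x; map back
      out[idx[order(gm[idx])]] <- ks$y
      bad <- !is.finite(out)
      out[bad] <- p[bad]
      out
    }
    b0 <- smooth_par(b0); b1 <- smooth_par(b1); lth <- smooth_par(lth)
  }
  theta <- 10^lth

  med_ld <- log10(pmax(median(depth), 1))
  values <- matrix(0, n_genes, ncol(m), dimnames = dimnames(m))
  resid <- matrix(0, n_genes, ncol(m), dimnames = dimnames(m))
  for (g in which(expressed)) {
    mu <- exp(b0[g] + b1[g] * ld)
    sdv <- sqrt(mu + mu^2 / theta[g])
    r <- (dense[g, ] - mu) / sdv
    mu_med <- exp(b0[g] + b1[g] * med_ld)
    sd_med <- sqrt(mu_med + mu_med^2 / theta[g])
    corrected <- pmax(mu_med + r * sd_med, 0)
    values[g, ] <- log2(corrected + 1)
    resid[g, ] <- r
  }
  model <- data.frame(gene_id = gene_ids,
                      intercept = ifelse(expressed, b0, 0),
                      depth_coef = ifelse(expressed, b1, 0),
                      theta = ifelse(expressed, theta, 0))
  list(values = values, residuals = resid, model = model, cell_depth = depth)
}

#' Depth-scaling log normalization
#'
#' Simple comparator normalization: counts are rescaled to the median cell
#' depth and log2(x + 1) transformed. Used by the benchmark harness as the
#' "no vst" arm.
#'
#' @inheritParams vst_normalize
#' @return genes x cells matrix of log2-scale values.
#' @export
depth_normalize <- function(counts) {
  m <- if (is.list(counts) && !is.null(counts$counts)) counts$counts else counts
  m <- as.matrix(m)
  depth <- pmax(colSums(m), 1)
  log2(1 + sweep(m, 2, median(depth) / depth, `*`))
}
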