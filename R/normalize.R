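#' Depth-normalize and log-transform counts
#'
#' Standard library-size normalization: each count is divided by its
#' cell's total, multiplied by `scale_factor` and transformed as
#' log(1 + x) (natural log). The result is invariant to per-cell depth
#' scaling and strictly monotone in counts within a cell.
#'
#' @param counts Genes x cells integer matrix.
#' @param scale_factor Target per-cell depth (default 1e4).
#' @return Matrix of normalized values with attribute `scale_factor`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- validate_counts(counts)
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("all-zero cell(s) present: run filter_cells()/filter_genes() first")
  v <- log1p(sweep(counts, 2L, tot, "/") * scale_factor)
  attr(v, "scale_factor") <- scale_factor
  v
}

#' Mean-variance ('vst') variable-gene statistics
#'
#' Computes, on raw counts, each gene's mean and variance, fits a local
#' polynomial trend of log10(variance) on log10(mean) (span 0.3) over
#' genes with positive variance, standardizes each gene's counts by the
#' trend-expected standard deviation with values clipped at
#' sqrt(n_cells), and reports the variance of the clipped standardized
#' values. Genes with zero variance score 0.
#'
#' @param counts Genes x cells integer matrix.
#' @return data.frame ranked by decreasing standardized variance (ties by
#'   gene id): `gene_id`, `mean`, `variance`, `variance_standardized`.
#' @export
variable_gene_stats <- function(counts) {
  counts <- validate_counts(counts)
  n <- ncol(counts)
  mu <- rowMeans(counts)
  v <- rowSums((counts - mu)^2) / (n - 1L)
  vs <- numeric(nrow(counts))
  fit_idx <- which(v > 0 & mu > 0)
  if (length(fit_idx) > 0L) {
    lx <- log10(mu[fit_idx]); ly <- log10(v[fit_idx])
    exp_sd <- if (length(fit_idx) >= 30L && length(unique(lx)) >= 5L) {
      fit <- stats::loess(ly ~ lx, span = 0.3,
                          control = stats::loess.control(surface = "direct"))
      sqrt(10^stats::fitted(fit))
    } else {
      ## too few genes for a stable local fit: fall back to a line
      fit <- stats::lm(ly ~ lx)
      sqrt(10^stats::fitted(fit))
    }
    clip <- sqrt(n)
    for (k in seq_along(fit_idx)) {
      i <- fit_idx[k]
      z <- pmin(pmax((counts[i, ] - mu[i]) / exp_sd[k], -clip), clip)
      vs[i] <- sum((z - mean(z))^2) / (n - 1L)
    }
  }
  out <- data.frame(gene_id = rownames(counts), mean = mu, variance = v,
                    variance_standardized = vs, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$variance_standardized, out$gene_id), , drop = FALSE]
}

#' Select the most variable genes
#'
#' @param counts Genes x cells integer matrix.
#' @param n Number of genes to return (default 2000). If `n` exceeds the
#'   number of genes, all genes are returned with a warning.
#' @return Character vector of gene ids, most variable first.
#' @export
select_variable_genes <- function(counts, n = 2000L) {
  st <- variable_gene_stats(counts)
  if (n > nrow(st)) {
    warning("n exceeds the number of genes; returning all genes")
    n <- nrow(st)
  }
  st$gene_id[seq_len(n)]
}

#' Scale normalized expression, optionally regressing out a covariate
#'
#' Per gene: if a covariate (for example the number of expressed genes
#' per cell) is supplied, values are replaced by the residuals of an
#' ordinary least-squares fit on it; each gene is then centred to mean 0
#' and scaled to unit variance (population variance, divisor n), with
#' constant genes mapped to an all-zero row, and values clipped to
#' `[-clip, clip]`.
#'
#' @param nm Normalized matrix from [log_normalize()].
#' @param covariate Optional numeric vector, one value per cell.
#' @param clip Clipping bound in standard deviations (default 10).
#' @return Scaled genes x cells matrix.
#' @export
scale_data <- function(nm, covariate = NULL, clip = 10) {
  nm <- as.matrix(nm)
  n <- ncol(nm)
  if (!is.null(covariate)) {
    if (length(covariate) != n)
      stop("covariate length must equal the number of cells")
    X <- cbind(1, as.numeric(covariate))
    ## residuals for all genes at once: nm - B X', B = nm X (X'X)^-1
    B <- nm %*% X %*% solve(crossprod(X))
    nm <- nm - B %*% t(X)
  }
  mu <- rowMeans(nm)
  sd_pop <- sqrt(rowSums((nm - mu)^2) / n)
  ## genes constant up to regression round-off scale to an all-zero row
  tol <- 1e-10 * max(1, max(abs(nm)))
  const <- sd_pop <= tol
  z <- (nm - mu) / ifelse(const, 1, sd_pop)
  z[const, ] <- 0
  pmin(pmax(z, -clip), clip)
}
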