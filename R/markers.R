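#' Log2 fold change between groups of normalized values
#'
#' Values are de-logged (expm1), averaged per group, offset by a
#' pseudocount and compared on the log2 scale:
#' log2((mean_in + pc) / (mean_out + pc)).
#'
#' @param v_in,v_out Normalized (log-scale) expression values.
#' @param pseudocount Offset (default 1).
#' @return The log2 fold change.
#' @export
log2_fold_change <- function(v_in, v_out, pseudocount = 1) {
  log2((mean(expm1(v_in)) + pseudocount) /
       (mean(expm1(v_out)) + pseudocount))
}

#' Marker genes / differentially expressed genes by Wilcoxon rank-sum
#'
#' For each contrast, genes are pre-filtered to those detected in more
#' than `min_pct` of cells in at least one of the two groups and with a
#' log2 fold change above `min_lfc` (one-vs-rest reports positive markers
#' only; a pairwise contrast reports both signs, i.e. |log2FC| >
#' `min_lfc`). Surviving genes are tested with [wilcoxon_test()] and
#' Bonferroni-adjusted over the total number of genes in the matrix, the
#' convention of the standard single-cell toolchain. Records with
#' adjusted p below `alpha` are returned sorted by p then gene id.
#'
#' @param nm Normalized matrix from [log_normalize()] (genes x cells).
#' @param groups Character/factor vector of group labels, one per cell.
#' @param contrast "one-vs-rest", or a length-2 character vector
#'   `c(groupA, groupB)` for a pairwise contrast.
#' @param min_pct Detection-fraction threshold (strict >; default 0.10).
#' @param min_lfc log2 fold-change threshold (strict >; default 0.25).
#' @param alpha Adjusted-p cutoff (strict <; default 0.05).
#' @param pseudocount Passed to [log2_fold_change()].
#' @return data.frame of marker records: `gene_id`, `group`, `log2fc`,
#'   `pct_in`, `pct_out`, `p`, `p_adj`.
#' @export
find_markers <- function(nm, groups, contrast = "one-vs-rest",
                         min_pct = 0.10, min_lfc = 0.25, alpha = 0.05,
                         pseudocount = 1) {
  nm <- as.matrix(nm)
  groups <- as.character(groups)
  if (length(groups) != ncol(nm))
    stop("`groups` must have one label per cell")
  tab <- table(groups)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L)
    stop("group(s) with fewer than 2 cells: ", paste(small, collapse = ", "))
  n_genes_total <- nrow(nm)

  contrasts <- if (identical(contrast, "one-vs-rest")) {
    lapply(sort(names(tab)), function(g)
      list(group = g, incl = groups == g, excl = groups != g, signed = FALSE))
  } else {
    stopifnot(length(contrast) == 2L, all(contrast %in% names(tab)))
    list(list(group = paste(contrast, collapse = "_vs_"),
              incl = groups == contrast[1L], excl = groups == contrast[2L],
              signed = TRUE))
  }

  out <- list()
  for (ct in contrasts) {
    min_ <- nm[, ct$incl, drop = FALSE]
    mout <- nm[, ct$excl, drop = FALSE]
    pct_in <- rowMeans(min_ > 0)
    pct_out <- rowMeans(mout > 0)
    ein <- rowMeans(expm1(min_)); eout <- rowMeans(expm1(mout))
    lfc <- log2((ein + pseudocount) / (eout + pseudocount))
    keep <- (pct_in > min_pct | pct_out > min_pct) &
      (if (ct$signed) abs(lfc) > min_lfc else lfc > min_lfc)
    idx <- which(keep)
    if (length(idx) == 0L) next
    p <- vapply(idx, function(i)
      wilcoxon_test(min_[i, ], mout[i, ]), numeric(1))
    rec <- data.frame(gene_id = rownames(nm)[idx], group = ct$group,
                      log2fc = lfc[idx], pct_in = pct_in[idx],
                      pct_out = pct_out[idx], p = p,
                      p_adj = pmin(1, p * n_genes_total),
                      stringsAsFactors = FALSE)
    rec <- rec[rec$p_adj < alpha, , drop = FALSE]
    rec <- rec[order(rec$p, rec$gene_id), , drop = FALSE]
    out[[ct$group]] <- rec
  }
  res <- if (length(out) > 0L) do.call(rbind, out)
    else data.frame(gene_id = character(0), group = character(0),
                    log2fc = numeric(0), pct_in = numeric(0),
                    pct_out = numeric(0), p = numeric(0), p_adj = numeric(0),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Pseudo-bulk expression by group
#'
#' Per gene and group, the mean of de-logged (expm1) normalized values
#' over the group's cells. Groups are ordered lexicographically.
#'
#' @param nm Normalized matrix (genes x cells).
#' @param groups Group label per cell.
#' @return Genes x groups matrix.
#' @export
pseudo_bulk <- function(nm, groups) {
  nm <- as.matrix(nm)
  groups <- as.character(groups)
  if (length(groups) != ncol(nm))
    stop("`groups` must have one label per cell")
  gl <- sort(unique(groups))
  e <- expm1(nm)
  out <- vapply(gl, function(g)
    rowMeans(e[, groups == g, drop = FALSE]), numeric(nrow(nm)))
  dimnames(out) <- list(rownames(nm), gl)
  out
}

#' Detection fraction by group
#'
#' Fraction of each group's cells in which a gene is detected
#' (normalized value > 0).
#'
#' @inheritParams pseudo_bulk
#' @return Genes x groups matrix of fractions.
#' @export
detection_fraction <- function(nm, groups) {
  nm <- as.matrix(nm)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  out <- vapply(gl, function(g)
    rowMeans(nm[, groups == g, drop = FALSE] > 0), numeric(nrow(nm)))
  dimnames(out) <- list(rownames(nm), gl)
  out
}
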