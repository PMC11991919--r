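## Canonical stage vocabularies; unknown labels sort after these,
## alphabetically.
STAGE_LEVELS <- c("8C", "16C", "16-32C", "EB", "MB", "LB",
                  "E3", "E3.5", "E4", "E4.5", "E5", "E6", "E7")

stage_order <- function(x) {
  u <- unique(x)
  u[order(match(u, STAGE_LEVELS, nomatch = length(STAGE_LEVELS) + 1L), u)]
}

#' Mutual nearest neighbours between two datasets
#'
#' Finds, for every cell of each dataset, its `k` nearest cross-dataset
#' neighbours by Euclidean distance on the shared feature axis, and
#' returns the pairs in which each cell is among the other's neighbours.
#' Neighbour ties are broken by cell-id order, so the result does not
#' depend on column ordering. A Pearson correlation over the shared
#' features is reported per pair.
#'
#' @param a,b Features x cells matrices with identical rownames
#'   (e.g. scaled expression on the ortholog axis).
#' @param k Neighbourhood size (default 20); capped at the dataset sizes
#'   with a warning.
#' @return data.frame of pairs: `cell_a`, `cell_b`, `distance`,
#'   `pearson_r`, ordered by `cell_a` then `cell_b`.
#' @export
mnn_pairs <- function(a, b, k = 20L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(rownames(a), rownames(b)))
    stop("`a` and `b` must share an identical feature axis (rownames)")
  stopifnot(k >= 1L)
  na <- ncol(a); nb <- ncol(b)
  if (k > na || k > nb) {
    warning("k exceeds a dataset size; capped at min(ncol(a), ncol(b))")
    k <- min(na, nb)
  }
  d2 <- outer(colSums(a^2), colSums(b^2), "+") - 2 * crossprod(a, b)
  d2[d2 < 0] <- 0                      # numerical noise
  d <- sqrt(d2)                        # na x nb

  knn_of <- function(dist_rows, ids) {
    ## per row: indices of the k smallest entries, ties by id order
    nn <- apply(dist_rows, 1L, function(v) order(v, ids)[seq_len(k)])
    if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
  }
  nn_ab <- knn_of(d, colnames(b))      # for each a-cell: b neighbours
  nn_ba <- knn_of(t(d), colnames(a))   # for each b-cell: a neighbours

  pairs <- list()
  for (i in seq_len(na)) {
    for (j in nn_ab[i, ]) {
      if (i %in% nn_ba[j, ])
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (length(pairs) == 0L)
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      distance = numeric(0), pearson_r = numeric(0),
                      stringsAsFactors = FALSE))
  pm <- do.call(rbind, pairs)
  out <- data.frame(cell_a = colnames(a)[pm[, 1L]],
                    cell_b = colnames(b)[pm[, 2L]],
                    # direct evaluation: exact zeros for identical cells
                    distance = vapply(seq_len(nrow(pm)), function(r)
                      sqrt(sum((a[, pm[r, 1L]] - b[, pm[r, 2L]])^2)),
                      numeric(1)),
                    pearson_r = vapply(seq_len(nrow(pm)), function(r)
                      stats::cor(a[, pm[r, 1L]], b[, pm[r, 2L]]), numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_a, out$cell_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage (or lineage) correspondence of MNN pairs
#'
#' Cross-tabulates the metadata labels of the two cells of every MNN
#' pair. Row/column order follows the canonical developmental-stage
#' vocabulary, then alphabetical.
#'
#' @param pairs Output of [mnn_pairs()].
#' @param meta_a,meta_b data.frames with columns `cell_id` and the
#'   label column.
#' @param label Metadata column to tabulate (default "stage").
#' @return Integer contingency matrix (labels of A x labels of B); its
#'   total equals `nrow(pairs)`.
#' @export
stage_correspondence <- function(pairs, meta_a, meta_b, label = "stage") {
  ia <- match(pairs$cell_a, meta_a$cell_id)
  ib <- match(pairs$cell_b, meta_b$cell_id)
  if (anyNA(ia) || anyNA(ib))
    stop("MNN pair cell id(s) missing from metadata")
  la <- factor(meta_a[[label]][ia], levels = stage_order(meta_a[[label]]))
  lb <- factor(meta_b[[label]][ib], levels = stage_order(meta_b[[label]]))
  as.matrix(table(la, lb))
}
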