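#' Read an ortholog table
#'
#' TSV with columns `gene_a`, `gene_b`, `homology_type` (Ensembl-style,
#' e.g. "ortholog_one2one", "ortholog_one2many").
#'
#' @param path TSV file.
#' @return data.frame with those three columns.
#' @export
read_ortholog_table <- function(path) {
  ot <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "homology_type") %in% colnames(ot)))
  ot
}

#' Restrict two expression matrices to their one-to-one orthologs
#'
#' Filters the ortholog table to `ortholog_one2one` records, intersects
#' it with the gene axes of both matrices and returns both matrices
#' restricted and reordered onto the shared ortholog axis. Row names of
#' the returned matrices are the ortholog keys `"gene_a|gene_b"`, so the
#' two matrices share a feature axis.
#'
#' @param nm_a,nm_b Genes x cells matrices for species A and B.
#' @param ot Ortholog table (see [read_ortholog_table()]).
#' @param symbol_fallback If `TRUE`, genes with identical row names in
#'   both matrices that the one2one table leaves unmapped are paired by
#'   name as well (the "same gene names" convention some marker
#'   comparisons use). Off by default: name matching is fragile under
#'   annotation drift.
#' @return List with `a`, `b` (reordered matrices) and `map` (data.frame
#'   `gene_a`, `gene_b`, `ortholog_key`).
#' @export
align_orthologs <- function(nm_a, nm_b, ot, symbol_fallback = FALSE) {
  ot <- ot[ot$homology_type == "ortholog_one2one",
           c("gene_a", "gene_b"), drop = FALSE]
  if (anyDuplicated(ot$gene_a) || anyDuplicated(ot$gene_b))
    stop("one2one ortholog table has duplicated gene ids")
  if (symbol_fallback) {
    shared <- setdiff(intersect(rownames(nm_a), rownames(nm_b)),
                      c(ot$gene_a, ot$gene_b))
    if (length(shared) > 0L)
      ot <- rbind(ot, data.frame(gene_a = shared, gene_b = shared,
                                 stringsAsFactors = FALSE))
  }
  keep <- ot$gene_a %in% rownames(nm_a) & ot$gene_b %in% rownames(nm_b)
  ot <- ot[keep, , drop = FALSE]
  if (nrow(ot) == 0L)
    stop("no one2one orthologs shared between the two matrices")
  ot <- ot[order(ot$gene_a), , drop = FALSE]
  key <- paste(ot$gene_a, ot$gene_b, sep = "|")
  a <- nm_a[ot$gene_a, , drop = FALSE]
  b <- nm_b[ot$gene_b, , drop = FALSE]
  rownames(a) <- key
  rownames(b) <- key
  list(a = a, b = b,
       map = data.frame(gene_a = ot$gene_a, gene_b = ot$gene_b,
                        ortholog_key = key, stringsAsFactors = FALSE))
}
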