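#' Read / write count matrices
#'
#' TSV layout: genes in rows (first column `gene_id`), cells in columns.
#' MatrixMarket layout: `.mtx` plus two one-column id files (genes, then
#' cells).
#'
#' @param path TSV file.
#' @return Integer genes x cells matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  validate_counts(m)
}

#' @rdname read_counts_tsv
#' @param counts Genes x cells matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts_tsv
#' @param mtx_path,genes_path,cells_path MatrixMarket file and id files.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, cells_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(cells_path)
  storage.mode(m) <- "integer"
  validate_counts(m)
}

#' @rdname read_counts_tsv
#' @export
write_counts_mtx <- function(counts, mtx_path, genes_path, cells_path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), cells_path)
  invisible(mtx_path)
}

#' Read cell metadata
#'
#' TSV with at least `cell_id`; typically also `embryo_id`, `stage`,
#' `lineage`, `species`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_cell_meta <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot("cell_id" %in% colnames(meta))
  meta
}

#' Write a QC report as JSON
#'
#' @param report The `report` data.frame from [filter_cells()].
#' @param path Output path.
#' @export
write_qc_report_json <- function(report, path) {
  jsonlite::write_json(list(n_cells = nrow(report),
                            n_kept = sum(report$kept),
                            cells = report),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a marker table as TSV
#'
#' @param markers data.frame from [find_markers()].
#' @param path Output path.
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
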