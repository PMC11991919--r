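validate_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and cell ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

#' QC thresholds for cell filtering
#'
#' Defaults follow the filtering used for full-length preimplantation
#' embryo scRNA-seq: a cell must express more than 3,000 genes, have a
#' mitochondrial read fraction below 5% and a stress-granule gene read
#' fraction below 8.5%; all three inequalities are strict. Genes must be
#' detected in at least `min_cells_per_gene` cells to be retained.
#'
#' @param min_genes Minimum expressed-gene count (strict >).
#' @param max_mito_frac Maximum mitochondrial fraction (strict <).
#' @param max_stress_frac Maximum stress-granule fraction (strict <).
#' @param min_cells_per_gene Minimum cells per gene (inclusive >=).
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(min_genes = 3000L, max_mito_frac = 0.05,
                          max_stress_frac = 0.085, min_cells_per_gene = 3L) {
  stopifnot(min_genes > 0, max_mito_frac > 0, max_mito_frac < 1,
            max_stress_frac > 0, max_stress_frac < 1, min_cells_per_gene >= 0)
  structure(list(min_genes = as.integer(min_genes),
                 max_mito_frac = max_mito_frac,
                 max_stress_frac = max_stress_frac,
                 min_cells_per_gene = as.integer(min_cells_per_gene)),
            class = "QCThresholds")
}

#' Gene sets used for QC fractions
#'
#' @param mito_genes,stress_genes Character vectors of gene ids. Ids
#'   absent from a count matrix are tolerated with a warning at use time.
#' @return A `GeneSets` list.
#' @export
gene_sets <- function(mito_genes = character(0), stress_genes = character(0)) {
  structure(list(mito_genes = unique(as.character(mito_genes)),
                 stress_genes = unique(as.character(stress_genes))),
            class = "GeneSets")
}

#' Bundled placeholder stress-granule gene list
#'
#' Human gene symbols of canonical stress-granule components, shipped so
#' the stress-fraction filter can be exercised without external inputs.
#' Real analyses should supply their own curated, species-mapped list
#' via [gene_sets()]; this placeholder is not a substitute for one.
#'
#' @return Character vector of gene symbols.
#' @export
placeholder_stress_genes <- function() {
  utils::read.delim(system.file("extdata",
                                "stress_granule_genes_placeholder.tsv",
                                package = "xembryo", mustWork = TRUE),
                    header = TRUE, stringsAsFactors = FALSE)$gene_name
}

#' Per-cell QC metrics
#'
#' Computes, on raw counts, the number of detected genes per cell and the
#' fraction of counts attributable to the mitochondrial and stress-granule
#' gene sets. A cell with zero total counts has both fractions defined as
#' 1 so that it fails every fraction filter.
#'
#' @param counts Genes x cells integer matrix with dimnames.
#' @param gs A [gene_sets()] object.
#' @return data.frame: `cell_id`, `n_genes`, `mito_frac`, `stress_frac`.
#' @export
compute_qc_metrics <- function(counts, gs) {
  counts <- validate_counts(counts)
  miss <- setdiff(c(gs$mito_genes, gs$stress_genes), rownames(counts))
  if (length(miss) > 0L)
    warning(length(miss), " QC gene-set ids absent from the count matrix")
  tot <- colSums(counts)
  frac_of <- function(set) {
    s <- colSums(counts[rownames(counts) %in% set, , drop = FALSE])
    ifelse(tot == 0, 1, s / pmax(tot, 1))
  }
  data.frame(cell_id = colnames(counts),
             n_genes = colSums(counts > 0),
             mito_frac = frac_of(gs$mito_genes),
             stress_frac = frac_of(gs$stress_genes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' Keeps cells passing all three criteria of [qc_thresholds()]; column
#' order is preserved. The report records every cell's metrics and, for
#' dropped cells, which criteria failed.
#'
#' @param counts Genes x cells integer matrix.
#' @param gs A [gene_sets()] object.
#' @param th A [qc_thresholds()] object.
#' @return List with `counts` (filtered matrix) and `report` (data.frame
#'   with `kept` logical and `fail_reason`).
#' @export
filter_cells <- function(counts, gs, th = qc_thresholds()) {
  m <- compute_qc_metrics(counts, gs)
  pass_genes <- m$n_genes > th$min_genes
  pass_mito <- m$mito_frac < th$max_mito_frac
  pass_stress <- m$stress_frac < th$max_stress_frac
  kept <- pass_genes & pass_mito & pass_stress
  reason <- rep(NA_character_, nrow(m))
  fails <- cbind(low_genes = !pass_genes, high_mito = !pass_mito,
                 high_stress = !pass_stress)
  reason[!kept] <- apply(fails[!kept, , drop = FALSE], 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  if (!any(kept)) warning("no cells pass QC")
  m$kept <- kept
  m$fail_reason <- reason
  list(counts = counts[, kept, drop = FALSE], report = m)
}

#' Filter rarely detected genes
#'
#' @param counts Genes x cells integer matrix.
#' @param min_cells Keep genes detected (count > 0) in at least this many
#'   cells (inclusive; default 3).
#' @return The filtered matrix.
#' @export
filter_genes <- function(counts, min_cells = 3L) {
  counts <- validate_counts(counts)
  counts[rowSums(counts > 0) >= min_cells, , drop = FALSE]
}
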