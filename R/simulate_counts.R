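## Negative-binomial scRNA-seq simulator with lineage-structured means,
## planted markers / conserved genes, mitochondrial and stress-granule
## gene groups sized to hit target fractions in expectation, and cells
## planted to fail exactly one QC criterion each.

DEFAULT_STAGE_MAP <- list(
  gp    = c(prelineage = "8C", ICM = "EB", EPI = "MB", PE = "MB", TE = "LB"),
  human = c(prelineage = "E3", ICM = "E5", EPI = "E6", PE = "E6", TE = "E7"),
  mouse = c(prelineage = "8C", ICM = "E3.5", EPI = "E4.5", PE = "E4.5",
            TE = "E4.5"))

#' Design of a simulated expression experiment
#'
#' Defaults describe the simulator's reference conditions: three
#' blastocyst lineages of 30 cells each, 5,000 genes with baseline
#' negative-binomial expression (mean 5, dispersion 0.5, log-normal
#' per-cell depth with sd 0.3), 50 planted markers at 8-fold elevation
#' distributed round-robin over the lineages, mitochondrial and
#' stress-granule gene groups targeting 2.5% and 4% of counts, and 10
#' planted QC-failing cells that each violate exactly one filter.
#'
#' @param species Character vector of species labels.
#' @param lineages Named integer vector: cells per lineage (>= 2 each).
#' @param n_genes Total genes per species.
#' @param baseline_mean Baseline NB mean per gene.
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2); 0 gives
#'   deterministic rounded means (noiseless mode).
#' @param depth_sd SD of log-normal per-cell depth multipliers.
#' @param n_markers,marker_fold Planted one-lineage markers and their
#'   fold change (> 1).
#' @param conserved_map Optional named list: gene base id -> named
#'   character vector species -> lineage; species absent from the vector
#'   get near-zero expression of that gene. Overrides marker planting for
#'   those genes.
#' @param conserved_fold Fold elevation of conserved genes.
#' @param n_mito,n_stress Sizes of the mitochondrial and stress-granule
#'   gene groups.
#' @param mito_fraction_target,stress_fraction_target Expected count
#'   fractions for the two groups (each must be <= 0.5).
#' @param n_fail_qc Cells planted to fail QC, cycling through the three
#'   failure modes (too few genes, high mito, high stress).
#' @param stage_map Named list species -> named character vector
#'   lineage -> stage label.
#' @param seed Integer seed.
#' @return An `ExpressionDesign` list.
#' @export
expression_design <- function(species = "gp",
                              lineages = c(EPI = 30L, PE = 30L, TE = 30L),
                              n_genes = 5000L, baseline_mean = 5,
                              dispersion = 0.5, depth_sd = 0.3,
                              n_markers = 50L, marker_fold = 8,
                              conserved_map = NULL, conserved_fold = 8,
                              n_mito = 50L, n_stress = 100L,
                              mito_fraction_target = 0.025,
                              stress_fraction_target = 0.04,
                              n_fail_qc = 10L,
                              stage_map = DEFAULT_STAGE_MAP, seed = 1L) {
  stopifnot(all(lineages >= 2L), n_genes > n_mito + n_stress,
            marker_fold > 1, conserved_fold > 1, dispersion >= 0)
  if (mito_fraction_target > 0.5 || stress_fraction_target > 0.5 ||
      mito_fraction_target + stress_fraction_target >= 1)
    stop("infeasible mito/stress fraction targets")
  structure(as.list(environment()), class = "ExpressionDesign")
}

base_gene_ids <- function(design) {
  c(sprintf("MT%03d", seq_len(design$n_mito)),
    sprintf("SG%03d", seq_len(design$n_stress)),
    sprintf("G%04d", seq_len(design$n_genes - design$n_mito - design$n_stress)))
}

## Genes x lineages matrix of NB means for one species.
species_mean_matrix <- function(design, sp, base_ids) {
  lin <- names(design$lineages)
  mu <- matrix(design$baseline_mean, nrow = design$n_genes, ncol = length(lin),
               dimnames = list(base_ids, lin))
  marker_lineage <- character(0)
  if (is.null(design$conserved_map) && design$n_markers > 0L) {
    pool <- base_ids[startsWith(base_ids, "G")]
    mk <- pool[seq_len(design$n_markers)]
    marker_lineage <- stats::setNames(rep_len(lin, design$n_markers), mk)
    for (g in mk) mu[g, marker_lineage[g]] <- design$baseline_mean * design$marker_fold
  }
  if (!is.null(design$conserved_map)) {
    for (g in names(design$conserved_map)) {
      l <- design$conserved_map[[g]][sp]
      if (is.na(l)) mu[g, ] <- 0.01
      else mu[g, l] <- design$baseline_mean * design$conserved_fold
    }
  }
  ## size the mito / stress means to hit the target fractions in
  ## expectation, given the baseline + planted load
  rest <- mean(colSums(mu[!grepl("^MT|^SG", base_ids), , drop = FALSE]))
  fm <- design$mito_fraction_target; fs <- design$stress_fraction_target
  total <- rest / (1 - fm - fs)
  mu[grepl("^MT", base_ids), ] <- fm * total / design$n_mito
  mu[grepl("^SG", base_ids), ] <- fs * total / design$n_stress
  list(mu = mu, marker_lineage = marker_lineage)
}

draw_counts <- function(mu_vec, dispersion) {
  if (dispersion == 0) return(round(mu_vec))
  stats::rnbinom(length(mu_vec), size = 1 / dispersion, mu = mu_vec)
}

## Rescale a gene group's counts so its fraction reaches `target`.
inflate_group <- function(counts_vec, idx, target) {
  if (sum(counts_vec[idx]) == 0) counts_vec[idx] <- 1
  m <- sum(counts_vec[idx]); tot <- sum(counts_vec)
  k <- ceiling(target * (tot - m) / ((1 - target) * m))
  counts_vec[idx] <- counts_vec[idx] * max(k, 2)
  counts_vec
}

#' Simulate multi-species count matrices with known ground truth
#'
#' See [expression_design()] for the knobs. Cells planted to fail QC are
#' appended after the clean cells and each violates exactly one
#' criterion: detected genes are truncated to 40% of the gene universe,
#' or the mitochondrial (stress) group is inflated to ~10% (~12%) of the
#' cell's counts. Output is deterministic given the design's seed.
#'
#' @param design An [expression_design()].
#' @return List with `species` (per species: `counts`, `meta`,
#'   `gene_sets`), `ortholog_tables` (per species pair, one2one rows on
#'   the shared base ids; `NULL` for single-species designs), `manifest`
#'   (ground truth: `qc_pass`, `markers`, `conserved`) and `design`.
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "ExpressionDesign"))
  set.seed(design$seed)
  base_ids <- base_gene_ids(design)
  lin_of_cells <- rep(names(design$lineages), design$lineages)
  n_clean <- length(lin_of_cells)
  fail_mode <- rep_len(c("low_genes", "high_mito", "high_stress"),
                       design$n_fail_qc)
  fail_lineage <- rep_len(names(design$lineages), design$n_fail_qc)
  out_species <- list()
  manifest <- list(markers = NULL, conserved = NULL, qc_pass = list())

  for (sp in design$species) {
    mm <- species_mean_matrix(design, sp, base_ids)
    gene_ids <- paste0(sp, "_", base_ids)
    mito_idx <- grep("^MT", base_ids)
    stress_idx <- grep("^SG", base_ids)
    n_cells <- n_clean + design$n_fail_qc
    depth <- exp(stats::rnorm(n_cells, 0, design$depth_sd))
    counts <- matrix(0L, nrow = design$n_genes, ncol = n_cells,
                     dimnames = list(gene_ids,
                                     sprintf("%s_c%03d", sp, seq_len(n_cells))))
    cell_lineage <- c(lin_of_cells, fail_lineage)
    for (j in seq_len(n_cells)) {
      cv <- draw_counts(mm$mu[, cell_lineage[j]] * depth[j], design$dispersion)
      if (j > n_clean) {
        mode <- fail_mode[j - n_clean]
        if (mode == "low_genes") {
          keep <- sample.int(design$n_genes, round(0.4 * design$n_genes))
          cv[-keep] <- 0
        } else if (mode == "high_mito") {
          cv <- inflate_group(cv, mito_idx, 0.10)
        } else {
          cv <- inflate_group(cv, stress_idx, 0.12)
        }
      }
      counts[, j] <- as.integer(cv)
    }
    smap <- design$stage_map[[sp]]
    if (is.null(smap)) smap <- design$stage_map[[1L]]
    meta <- data.frame(
      cell_id = colnames(counts),
      embryo_id = sprintf("%s_emb%d", sp, ((seq_len(n_cells) - 1L) %% 5L) + 1L),
      stage = unname(smap[cell_lineage]),
      lineage = cell_lineage, species = sp, stringsAsFactors = FALSE)
    qc_pass <- c(rep(TRUE, n_clean), rep(FALSE, design$n_fail_qc))
    names(qc_pass) <- colnames(counts)
    manifest$qc_pass[[sp]] <- qc_pass
    if (is.null(manifest$markers) && length(mm$marker_lineage) > 0L)
      manifest$markers <- data.frame(gene = names(mm$marker_lineage),
                                     lineage = unname(mm$marker_lineage),
                                     stringsAsFactors = FALSE)
    out_species[[sp]] <- list(
      counts = counts, meta = meta,
      gene_sets = gene_sets(mito_genes = gene_ids[mito_idx],
                            stress_genes = gene_ids[stress_idx]))
  }

  if (!is.null(design$conserved_map)) {
    sps <- design$species
    lin <- t(vapply(names(design$conserved_map), function(g) {
      v <- design$conserved_map[[g]][sps]
      v[is.na(v)] <- "unexpressed"
      unname(v)
    }, character(length(sps))))
    colnames(lin) <- sps
    ## conservation categories are defined for three-species designs
    category <- if (length(sps) == 3L)
      apply(lin, 1L, planted_category, species = sps)
    else NA_character_
    manifest$conserved <- data.frame(
      gene = names(design$conserved_map), lin, category = category,
      stringsAsFactors = FALSE, row.names = NULL)
  }

  ortholog_tables <- NULL
  if (length(design$species) > 1L) {
    ortholog_tables <- list()
    prs <- utils::combn(design$species, 2L, simplify = FALSE)
    for (p in prs) {
      ortholog_tables[[paste(p, collapse = "_")]] <- data.frame(
        gene_a = paste0(p[1L], "_", base_ids),
        gene_b = paste0(p[2L], "_", base_ids),
        homology_type = "ortholog_one2one", stringsAsFactors = FALSE)
    }
  }
  list(species = out_species, ortholog_tables = ortholog_tables,
       manifest = manifest, design = design)
}

## Ground-truth category of a planted lineage vector (first, second,
## third species), mirroring the documented conservation rule.
planted_category <- function(l, species) {
  pair_names <- c(paste(species[1L], species[3L], "only", sep = "_"),
                  paste(species[2L], species[3L], "only", sep = "_"),
                  paste(species[1L], species[2L], "only", sep = "_"))
  if (l[1L] != "unexpressed" && l[1L] == l[2L] && l[2L] == l[3L])
    return("all_three")
  if (l[1L] != "unexpressed" && l[1L] == l[3L]) return(pair_names[1L])
  if (l[2L] != "unexpressed" && l[2L] == l[3L]) return(pair_names[2L])
  if (l[1L] != "unexpressed" && l[1L] == l[2L]) return(pair_names[3L])
  "none"
}

#' A planted three-species conservation design
#'
#' Convenience wrapper building an [expression_design()] whose
#' `conserved_map` plants `n_per_category` genes in each conservation
#' category over the lineages EPI, PE and TE (the `none` genes are
#' assigned a different lineage in every species).
#'
#' @param n_per_category Genes per category (default 20).
#' @param species The three species labels.
#' @param dispersion,depth_sd,seed Passed through; `dispersion = 0` gives
#'   the noiseless variant.
#' @param ... Further arguments to [expression_design()].
#' @return An `ExpressionDesign`.
#' @export
conservation_design <- function(n_per_category = 20L,
                                species = c("human", "mouse", "gp"),
                                dispersion = 0.5, depth_sd = 0.3,
                                seed = 1L, ...) {
  lins <- c("EPI", "PE", "TE")
  cmap <- list()
  add <- function(cmap, maker) {
    for (i in seq_len(n_per_category)) {
      l <- lins[((i - 1L) %% 3L) + 1L]
      cmap[[sprintf("G%04d", length(cmap) + 1L)]] <- maker(l)
    }
    cmap
  }
  cmap <- add(cmap, function(l) stats::setNames(c(l, l, l), species))
  cmap <- add(cmap, function(l) stats::setNames(c(l, NA, l), species))
  cmap <- add(cmap, function(l) stats::setNames(c(NA, l, l), species))
  cmap <- add(cmap, function(l) stats::setNames(c(l, l, NA), species))
  ## 'none': every species assigned a different lineage
  cmap <- add(cmap, function(l) stats::setNames(c("EPI", "PE", "TE"), species))
  expression_design(species = species,
                    lineages = c(EPI = 20L, PE = 20L, TE = 20L),
                    conserved_map = cmap, n_markers = 0L,
                    n_fail_qc = 0L, dispersion = dispersion,
                    depth_sd = depth_sd, seed = seed, ...)
}
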