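## Fixed lineage order used for deterministic tie-breaking.
LINEAGE_ORDER <- c("prelineage", "ICM", "EPI", "PE", "TE")

#' Assign each gene to its highest-expressing lineage
#'
#' A gene is considered a lineage gene if its pseudo-bulk mean is
#' strictly greatest in that lineage and the gene is detected in more
#' than `min_pct` of that lineage's cells; otherwise it is
#' "unexpressed". Exact ties on the maximum are flagged (`tied = TRUE`)
#' and broken by the fixed lineage order prelineage < ICM < EPI < PE <
#' TE. All-zero genes are "unexpressed".
#'
#' @param pb Genes x lineages pseudo-bulk matrix (see [pseudo_bulk()]).
#' @param pct Genes x lineages detection-fraction matrix (see
#'   [detection_fraction()]); same dimnames as `pb`.
#' @param min_pct Detection threshold (strict >; default 0.10).
#' @param species Optional species label carried through to the output.
#' @return data.frame: `gene_id`, `species`, `lineage`,
#'   `pct_in_lineage`, `tied`.
#' @export
assign_lineage <- function(pb, pct, min_pct = 0.10, species = NA_character_) {
  stopifnot(identical(dim(pb), dim(pct)),
            identical(colnames(pb), colnames(pct)))
  lin <- colnames(pb)
  ord <- order(match(lin, LINEAGE_ORDER, nomatch = length(LINEAGE_ORDER) + 1L), lin)
  pb <- pb[, ord, drop = FALSE]; pct <- pct[, ord, drop = FALSE]
  lin <- colnames(pb)
  rows <- lapply(seq_len(nrow(pb)), function(i) {
    v <- pb[i, ]
    if (all(v == 0))
      return(data.frame(gene_id = rownames(pb)[i], species = species,
                        lineage = "unexpressed", pct_in_lineage = 0,
                        tied = FALSE, stringsAsFactors = FALSE))
    mx <- max(v)
    top <- which(v == mx)
    j <- top[1L]                       # fixed lineage order breaks ties
    tied <- length(top) > 1L
    ok <- pct[i, j] > min_pct
    data.frame(gene_id = rownames(pb)[i], species = species,
               lineage = if (ok) lin[j] else "unexpressed",
               pct_in_lineage = pct[i, j], tied = tied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify cross-species conservation of lineage assignment
#'
#' Given per-species lineage assignments keyed by a shared ortholog key,
#' each key is placed in exactly one category: `all_three` when all
#' three species agree on the same non-"unexpressed" lineage; a pairwise
#' category when exactly that pair agrees on a non-"unexpressed" lineage
#' and the third species differs or is unexpressed; `none` otherwise. A
#' key missing from a species is treated as "unexpressed" there.
#'
#' @param assignments Named list of three named character vectors
#'   (ortholog key -> lineage), in the order first, second, third
#'   species; default naming expects human, mouse, gp.
#' @return List with `records` (data.frame: `ortholog_key`, one lineage
#'   column per species, `category`) and `counts` (named integer vector
#'   over the five categories).
#' @export
classify_conservation <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) == 3L,
            !is.null(names(assignments)))
  sp <- names(assignments)
  keys <- sort(unique(unlist(lapply(assignments, names))))
  lin <- vapply(assignments, function(a) {
    v <- unname(a[keys])
    v[is.na(v)] <- "unexpressed"
    v
  }, character(length(keys)))
  if (length(keys) == 1L) lin <- matrix(lin, nrow = 1L,
                                        dimnames = list(NULL, sp))
  cat_pairs <- list(c(1L, 3L), c(2L, 3L), c(1L, 2L))
  pair_names <- vapply(cat_pairs, function(p)
    paste(sp[p[1L]], sp[p[2L]], "only", sep = "_"), "")
  category <- vapply(seq_along(keys), function(i) {
    l <- lin[i, ]
    if (l[1L] != "unexpressed" && l[1L] == l[2L] && l[2L] == l[3L])
      return("all_three")
    for (k in seq_along(cat_pairs)) {
      p <- cat_pairs[[k]]
      if (l[p[1L]] != "unexpressed" && l[p[1L]] == l[p[2L]])
        return(pair_names[k])
    }
    "none"
  }, "")
  records <- data.frame(ortholog_key = keys, lin, category,
                        stringsAsFactors = FALSE, row.names = NULL)
  colnames(records) <- c("ortholog_key", sp, "category")
  counts <- stats::setNames(integer(5L), c("all_three", pair_names, "none"))
  tab <- table(category)
  counts[names(tab)] <- as.integer(tab)
  list(records = records, counts = counts)
}
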