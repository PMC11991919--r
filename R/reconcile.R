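#' Filter classified transfrags
#'
#' Applies the three exclusion rules used when repairing the annotation:
#' transfrags shorter than `min_length` bp of exonic sequence, transfrags
#' with class code 'e', 's' or 'x', and transfrags with same-strand
#' exonic overlap with two or more distinct reference genes are removed.
#' "Less than" is strict: a 200-bp transfrag is kept at the default.
#'
#' @param results Classification data.frame from [classify_transfrags()].
#' @param transfrags The matching list of [transfrag()] objects.
#' @param min_length Minimum exonic length in bp (default 200).
#' @return List with `kept` (transfrags, input order preserved) and
#'   `dropped`, a data.frame of `transfrag_id` and `reason` (one of
#'   `short`, `class_esx`, `multigene`).
#' @export
filter_transfrags <- function(results, transfrags, min_length = 200L) {
  ids <- vapply(transfrags, `[[`, "", "transfrag_id")
  if (!setequal(ids, results$transfrag_id) || length(ids) != nrow(results))
    stop("transfrag ids in `results` and `transfrags` do not match")
  results <- results[match(ids, results$transfrag_id), , drop = FALSE]

  len <- vapply(transfrags, function(t) exon_length(t$exons), integer(1))
  reason <- rep(NA_character_, length(ids))
  reason[len < min_length] <- "short"
  reason[is.na(reason) & results$code %in% c("e", "s", "x")] <- "class_esx"
  reason[is.na(reason) & results$n_overlapping_genes >= 2L] <- "multigene"

  list(kept = transfrags[is.na(reason)],
       dropped = data.frame(transfrag_id = ids[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}

#' Read BLAST tabular hits with a subject gene-name sidecar
#'
#' `hits_path` is standard 12-column tabular output (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore);
#' `subjects_path` is a TSV mapping subject ids to gene names and species
#' (columns `subject_id`, `gene_name`, `species`). Only the single best
#' hit per query (highest bitscore, ties by subject id) is retained,
#' mirroring a search run with max_target_seqs 1 and max_hsps 1.
#'
#' @param hits_path BLAST outfmt-6 TSV.
#' @param subjects_path Subject-to-gene-name TSV.
#' @return A data.frame of alignment hits: `query_id`,
#'   `subject_transcript_id`, `subject_gene_name`, `subject_species`,
#'   `evalue`, `bitscore`, `pct_identity`.
#' @export
read_blast_hits <- function(hits_path, subjects_path) {
  h <- utils::read.delim(hits_path, header = FALSE, stringsAsFactors = FALSE)
  colnames(h) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")
  s <- utils::read.delim(subjects_path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "gene_name", "species") %in% colnames(s)))
  h <- h[order(h$qseqid, -h$bitscore, h$sseqid), , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  i <- match(h$sseqid, s$subject_id)
  data.frame(query_id = h$qseqid, subject_transcript_id = h$sseqid,
             subject_gene_name = s$gene_name[i],
             subject_species = s$species[i],
             evalue = h$evalue, bitscore = h$bitscore,
             pct_identity = h$pident, stringsAsFactors = FALSE)
}

#' Resolve the disposition of a novel ('u' or 'i') transfrag
#'
#' Novel transfrags are resolved with the help of a best cross-species
#' alignment hit: with no hit the transfrag is retained as an unnamed
#' novel gene; a hit to a gene with no counterpart in the current
#' annotation founds a new gene named after the subject; a hit to a gene
#' already annotated merges the transfrag into that gene provided it lies
#' within the gene's locus extended by `window` bp on both sides, and is
#' otherwise retained as an unnamed novel gene.
#'
#' @param t A [transfrag()].
#' @param code Its class code; must be "u" or "i".
#' @param best_hit One row of [read_blast_hits()] output, or `NULL`.
#' @param refs The current [annotation_set()].
#' @param ortholog_names Named character vector mapping subject gene names
#'   to gene ids in `refs` (absent name = no known ortholog).
#' @param window Locus extension in bp (default 3000).
#' @param max_evalue Hits worse than this are rejected (default 1e-20).
#' @return List with `disposition` (one of `novel_retained_unnamed`,
#'   `novel_named_new_gene`, `novel_merged_within_3kb`), `gene_id` and
#'   `gene_name`.
#' @export
resolve_novel <- function(t, code, best_hit = NULL, refs, ortholog_names,
                          window = 3000L, max_evalue = 1e-20) {
  stopifnot(code %in% c("u", "i"))
  if (is.null(best_hit) || nrow(as.data.frame(best_hit)) == 0L)
    return(list(disposition = "novel_retained_unnamed",
                gene_id = NA_character_, gene_name = NA_character_))
  best_hit <- as.data.frame(best_hit)
  if (best_hit$evalue > max_evalue)
    stop("alignment hit for ", t$transfrag_id, " exceeds the e-value ",
         "threshold (", format(best_hit$evalue), " > ", format(max_evalue), ")")
  gp_gene <- unname(ortholog_names[best_hit$subject_gene_name])
  if (is.null(gp_gene) || length(gp_gene) == 0L || is.na(gp_gene) ||
      !gp_gene %in% refs$genes$gene_id)
    return(list(disposition = "novel_named_new_gene",
                gene_id = best_hit$subject_gene_name,
                gene_name = best_hit$subject_gene_name))
  g <- refs$genes[gp_gene, ]
  sp <- exon_span(t$exons)
  if (g$chrom == t$chrom &&
      sp[1L] >= g$start - window && sp[2L] <= g$end + window)
    return(list(disposition = "novel_merged_within_3kb",
                gene_id = gp_gene, gene_name = g$gene_name))
  list(disposition = "novel_retained_unnamed",
       gene_id = NA_character_, gene_name = NA_character_)
}

## Codes attached to their reference gene as additional transcripts.
## 'c' (transfrag contained in a reference transcript) is included: a
## fragment of a known transcript can only belong to that gene, and
## treating it as novel would misroute it through the alignment branch.
ASSIGN_CODES <- c("j", "k", "=", "m", "n", "o", "p", "y", "c")

## Deterministic transcript-id de-duplication: T, T_1, T_2, ...
unique_tx_id <- function(anno, id) {
  out <- id; k <- 0L
  while (out %in% names(anno$transcripts)) {
    k <- k + 1L
    out <- paste0(id, "_", k)
  }
  out
}

unique_gene_id <- function(anno, id) {
  out <- id; k <- 0L
  while (out %in% anno$genes$gene_id) {
    k <- k + 1L
    out <- paste0(id, "_", k)
  }
  out
}

#' Reconcile a reference annotation with assembled transfrags
#'
#' Full annotation-repair pipeline: classify every transfrag, drop short /
#' 'e','s','x' / multi-gene transfrags, attach transfrags with class codes
#' 'j', 'k', '=', 'm', 'n', 'o', 'p' or 'y' to their reference gene as
#' additional transcripts, resolve novel 'u'/'i' transfrags via alignment
#' hits (new named gene, merge within the +/- 3 kb window, or retain as an
#' unnamed novel gene), and finally merge the annotation of biotypes that
#' were never assembled. Transcript-id collisions are renamed with a
#' deterministic numeric suffix and logged in the disposition table.
#'
#' @param refs Reference [annotation_set()].
#' @param transfrags List of [transfrag()] objects.
#' @param hits Alignment-hit data.frame from [read_blast_hits()] (may have
#'   zero rows).
#' @param nonassembled [annotation_set()] of biotypes excluded from the
#'   assembly (miRNA, snRNA, ...); pass an empty set if none.
#' @param ortholog_names Named character vector: subject gene name ->
#'   existing gene id (see [resolve_novel()]).
#' @param min_length,window Filtering and merge parameters.
#' @return List with `annotation` (the reconciled [annotation_set()]),
#'   `report` (named integer vector of disposition counts) and
#'   `dispositions` (per-transfrag data.frame).
#' @export
reconcile <- function(refs, transfrags, hits = NULL,
                      nonassembled = annotation_set(),
                      ortholog_names = character(0),
                      min_length = 200L, window = 3000L) {
  out <- refs
  disp <- data.frame(transfrag_id = character(0), disposition = character(0),
                     code = character(0), gene_id = character(0),
                     stringsAsFactors = FALSE)

  if (length(transfrags) > 0L) {
    res <- classify_transfrags(transfrags, refs)
    flt <- filter_transfrags(res, transfrags, min_length = min_length)
    if (nrow(flt$dropped) > 0L) {
      disp <- rbind(disp, data.frame(
        transfrag_id = flt$dropped$transfrag_id,
        disposition = paste0("dropped_", flt$dropped$reason),
        code = res$code[match(flt$dropped$transfrag_id, res$transfrag_id)],
        gene_id = NA_character_, stringsAsFactors = FALSE))
    }
    hit_by_query <- if (!is.null(hits) && nrow(hits) > 0L)
      split(hits, hits$query_id) else list()

    for (t in flt$kept) {
      code <- res$code[res$transfrag_id == t$transfrag_id]
      ref_gene <- res$ref_gene_id[res$transfrag_id == t$transfrag_id]
      if (code %in% ASSIGN_CODES) {
        g <- out$genes[ref_gene, ]
        txid <- unique_tx_id(out, t$transfrag_id)
        tx <- transcript_model(txid, ref_gene, t$chrom,
                               if (t$strand == ".") g$strand else t$strand,
                               t$exons, biotype = "assembled")
        out <- add_transcript(out, tx)
        disp <- rbind(disp, data.frame(
          transfrag_id = t$transfrag_id,
          disposition = "assigned_to_reference_gene",
          code = code, gene_id = ref_gene, stringsAsFactors = FALSE))
      } else {  # 'u' or 'i'
        bh <- hit_by_query[[t$transfrag_id]]
        rn <- resolve_novel(t, code, bh, out, ortholog_names, window = window)
        if (rn$disposition == "novel_merged_within_3kb") {
          g <- out$genes[rn$gene_id, ]
          txid <- unique_tx_id(out, t$transfrag_id)
          tx <- transcript_model(txid, rn$gene_id, t$chrom,
                                 if (t$strand == ".") g$strand else t$strand,
                                 t$exons, biotype = "assembled")
          out <- add_transcript(out, tx)
          disp <- rbind(disp, data.frame(
            transfrag_id = t$transfrag_id, disposition = rn$disposition,
            code = code, gene_id = rn$gene_id, stringsAsFactors = FALSE))
        } else if (rn$disposition == "novel_named_new_gene") {
          gid <- unique_gene_id(out, rn$gene_id)
          txid <- unique_tx_id(out, t$transfrag_id)
          tx <- transcript_model(txid, gid, t$chrom,
                                 if (t$strand == ".") "+" else t$strand,
                                 t$exons, biotype = "assembled")
          out <- add_gene(out, tx, gene_name = rn$gene_name)
          disp <- rbind(disp, data.frame(
            transfrag_id = t$transfrag_id, disposition = rn$disposition,
            code = code, gene_id = gid, stringsAsFactors = FALSE))
        } else {
          gid <- unique_gene_id(out, paste0("NOVEL_", t$transfrag_id))
          txid <- unique_tx_id(out, t$transfrag_id)
          tx <- transcript_model(txid, gid, t$chrom,
                                 if (t$strand == ".") "+" else t$strand,
                                 t$exons, biotype = "assembled")
          out <- add_gene(out, tx)
          disp <- rbind(disp, data.frame(
            transfrag_id = t$transfrag_id, disposition = rn$disposition,
            code = code, gene_id = gid, stringsAsFactors = FALSE))
        }
      }
    }
  }

  n_nonasm <- 0L
  for (tx in nonassembled$transcripts) {
    nm <- nonassembled$genes[tx$gene_id, "gene_name"]
    txid <- unique_tx_id(out, tx$transcript_id)
    tx$transcript_id <- txid
    if (tx$gene_id %in% out$genes$gene_id) out <- add_transcript(out, tx)
    else out <- add_gene(out, tx, gene_name = nm)
    n_nonasm <- n_nonasm + 1L
  }

  report <- c(dropped_short = sum(disp$disposition == "dropped_short"),
              dropped_class_esx = sum(disp$disposition == "dropped_class_esx"),
              dropped_multigene = sum(disp$disposition == "dropped_multigene"),
              assigned_to_reference_gene =
                sum(disp$disposition == "assigned_to_reference_gene"),
              novel_named_new_gene =
                sum(disp$disposition == "novel_named_new_gene"),
              novel_merged_within_3kb =
                sum(disp$disposition == "novel_merged_within_3kb"),
              novel_retained_unnamed =
                sum(disp$disposition == "novel_retained_unnamed"),
              nonassembled_biotypes_merged = n_nonasm)
  stopifnot(sum(report[1:7]) == length(transfrags))
  list(annotation = out, report = report, dispositions = disp)
}

#' Write a reconciliation report as JSON
#'
#' @param report Named integer vector from [reconcile()].
#' @param path Output path.
#' @export
write_reconciliation_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
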