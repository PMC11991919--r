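## Toy-annotation fixture generator. Each planted class code is realized
## by an explicit construction against a four-exon reference transcript
## (exons [1000,1200) [1500,1700) [2000,2200) [2500,2700), strand '+'),
## placed on its own chromosome with a seeded random coordinate offset so
## cases can never interfere. Constructions, not rejection sampling: the
## requested code is guaranteed under the package's class-code dialect.

ref_case_exons <- function(off) exon_chain(off + c(1000L, 1500L, 2000L, 2500L),
                                           off + c(1200L, 1700L, 2200L, 2700L))

## Transfrag construction for each code, relative to the case offset.
code_construction <- function(code, off) {
  ex <- function(s, e, strand = "+") list(exons = exon_chain(off + s, off + e),
                                          strand = strand)
  switch(code,
    "=" = ex(c(950L, 1500L, 2000L, 2500L), c(1200L, 1700L, 2200L, 2750L)),
    "c" = ex(c(1550L, 2000L), c(1700L, 2100L)),
    "k" = ex(c(500L, 900L, 1500L, 2000L, 2500L, 3000L),
             c(700L, 1200L, 1700L, 2200L, 2700L, 3100L)),
    "m" = ex(c(1000L, 1500L), c(1200L, 2700L)),
    "n" = ex(1400L, 2100L),
    "j" = ex(c(1100L, 1500L, 1800L), c(1200L, 1650L, 1900L)),
    "e" = ex(1600L, 1750L),
    "o" = ex(c(1600L, 1850L), c(1750L, 1900L)),
    "s" = ex(c(1100L, 1500L), c(1200L, 1600L), strand = "-"),
    "x" = ex(1550L, 1650L, strand = "-"),
    "i" = ex(1750L, 1950L),
    "y" = ex(c(500L, 3000L), c(800L, 3300L)),
    "p" = ex(4200L, 4500L),
    "u" = ex(20000L, 20500L),
    stop("no construction for class code '", code, "'")
  )
}

#' Specification for a toy annotation fixture
#'
#' @param planted_codes Character vector (repeats allowed) of class codes
#'   to realize; defaults to one of each of the 14 codes.
#' @param seed Integer seed for the coordinate offsets.
#' @param u_hit_names Optional character vector of subject gene names,
#'   recycled over the planted 'u' cases; `NA` entries plant no hit.
#' @return An `AnnotationFixtureSpec` list.
#' @export
annotation_fixture_spec <- function(planted_codes = CLASS_CODE_ORDER,
                                    seed = 1L, u_hit_names = NA_character_) {
  bad <- setdiff(planted_codes, CLASS_CODE_ORDER)
  if (length(bad) > 0L)
    stop("unrealizable class code(s): ", paste(bad, collapse = ", "))
  structure(list(planted_codes = planted_codes, seed = as.integer(seed),
                 u_hit_names = u_hit_names),
            class = "AnnotationFixtureSpec")
}

#' Generate a toy annotation fixture with planted class codes
#'
#' @param spec An [annotation_fixture_spec()].
#' @return List with `refs` (reference [annotation_set()], one gene per
#'   case), `transfrags`, `hits` (alignment-hit data.frame, possibly
#'   empty), and `manifest` (data.frame `transfrag_id`, `code`).
#' @export
make_annotation_fixture <- function(spec) {
  stopifnot(inherits(spec, "AnnotationFixtureSpec"))
  set.seed(spec$seed)
  codes <- spec$planted_codes
  offs <- sample.int(5000L, length(codes), replace = TRUE)
  refs_tx <- list(); tfs <- list()
  hit_rows <- list()
  u_names <- rep_len(spec$u_hit_names, max(1L, sum(codes == "u")))
  u_seen <- 0L
  for (i in seq_along(codes)) {
    chrom <- sprintf("chr_case%02d", i)
    refs_tx[[i]] <- transcript_model(sprintf("REFT%02d", i),
                                     sprintf("REFG%02d", i),
                                     chrom, "+", ref_case_exons(offs[i]))
    con <- code_construction(codes[i], offs[i])
    tid <- sprintf("TF%02d", i)
    tfs[[i]] <- transfrag(tid, chrom, con$strand, con$exons)
    if (codes[i] == "u") {
      u_seen <- u_seen + 1L
      nm <- u_names[u_seen]
      if (!is.na(nm)) {
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = tid, subject_transcript_id = paste0("HS_", nm),
          subject_gene_name = nm, subject_species = "human",
          evalue = 1e-50, bitscore = 500, pct_identity = 95,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hit_rows) > 0L) do.call(rbind, hit_rows)
    else data.frame(query_id = character(0),
                    subject_transcript_id = character(0),
                    subject_gene_name = character(0),
                    subject_species = character(0), evalue = numeric(0),
                    bitscore = numeric(0), pct_identity = numeric(0),
                    stringsAsFactors = FALSE)
  list(refs = annotation_set(refs_tx), transfrags = tfs, hits = hits,
       manifest = data.frame(
         transfrag_id = vapply(tfs, `[[`, "", "transfrag_id"),
         code = codes, stringsAsFactors = FALSE))
}

#' Fixture exercising every reconciliation disposition
#'
#' Ten transfrags planted so that [reconcile()] produces at least one of
#' each disposition: an exact-match and a junction-sharing transfrag
#' (assigned), a 150-bp transfrag (dropped short), an opposite-strand
#' overlap (dropped e/s/x), a transfrag spanning two genes (dropped
#' multi-gene), a novel transfrag whose best hit names a gene absent from
#' the annotation (new named gene), one merging into an existing gene
#' within the 3-kb window, one whose ortholog lies beyond the window, one
#' with no hit, and an intronic novel transfrag; plus two non-assembled
#' miRNA genes merged at the end.
#'
#' @param seed Unused placeholder for interface symmetry (the fixture is
#'   fully deterministic).
#' @return List with `refs`, `transfrags`, `hits`, `ortholog_names`,
#'   `nonassembled` and `manifest` (expected disposition counts and the
#'   per-transfrag table).
#' @export
make_reconcile_fixture <- function(seed = 1L) {
  tx <- function(id, g, chrom, s, e, strand = "+", biotype = "protein_coding")
    transcript_model(id, g, chrom, strand, exon_chain(s, e), biotype)
  refs <- annotation_set(list(
    tx("TA", "GENE_A", "chrA", c(1000L, 1500L, 2000L, 2500L),
       c(1200L, 1700L, 2200L, 2700L)),
    tx("TB", "GENE_B", "chrB", c(1000L, 1500L, 2000L, 2500L),
       c(1200L, 1700L, 2200L, 2700L)),
    tx("TC", "GENE_C", "chrC", 1000L, 2000L),
    tx("TD", "GENE_D", "chrD", 1000L, 2000L),
    tx("TE1", "GENE_E1", "chrE", 1000L, 2000L),
    tx("TE2", "GENE_E2", "chrE", 3000L, 4000L),
    tx("TF", "GENE_F", "chrF", c(6000L, 7000L), c(6500L, 7500L)),
    tx("TG", "GENE_G", "chrG", c(6000L, 7000L), c(6500L, 7500L)),
    tx("TH", "GENE_H", "chrH", c(1000L, 3000L), c(1500L, 3500L))
  ))
  tf <- function(id, chrom, s, e, strand = "+")
    transfrag(id, chrom, strand, exon_chain(s, e))
  transfrags <- list(
    tf("T_eq", "chrA", c(1000L, 1500L, 2000L, 2500L),
       c(1200L, 1700L, 2200L, 2700L)),                    # '=' assigned
    tf("T_j", "chrB", c(1100L, 1500L, 1800L),
       c(1200L, 1650L, 1900L)),                           # 'j' assigned
    tf("T_short", "chrC", 1200L, 1350L),                  # 150 bp, dropped
    tf("T_x", "chrD", 1100L, 1400L, strand = "-"),        # 'x', dropped
    tf("T_multi", "chrE", 1500L, 3500L),                  # two genes, dropped
    tf("T_new", "chrN", 1000L, 1600L),                    # 'u' + hit, new gene
    tf("T_merge", "chrF", 4800L, 5200L),                  # 'u' within 3 kb
    tf("T_far", "chrG", 1500L, 2000L),                    # 'u' beyond 3 kb
    tf("T_nohit", "chrU", 1000L, 1400L),                  # 'u', no hit
    tf("T_intronic", "chrH", 1800L, 2300L)                # 'i', no hit
  )
  hits <- data.frame(
    query_id = c("T_new", "T_merge", "T_far"),
    subject_transcript_id = c("HS_SOX2_201", "HS_TBX3_201", "HS_GATA4_201"),
    subject_gene_name = c("SOX2", "TBX3", "GATA4"),
    subject_species = "human",
    evalue = c(1e-80, 1e-60, 1e-40), bitscore = c(800, 600, 400),
    pct_identity = c(96, 92, 90), stringsAsFactors = FALSE)
  ortholog_names <- c(TBX3 = "GENE_F", GATA4 = "GENE_G")
  nonassembled <- annotation_set(list(
    tx("MIR1_T", "MIR1", "chrM1", 100L, 200L, biotype = "miRNA"),
    tx("MIR2_T", "MIR2", "chrM2", 100L, 190L, biotype = "miRNA")
  ))
  manifest <- c(dropped_short = 1L, dropped_class_esx = 1L,
                dropped_multigene = 1L, assigned_to_reference_gene = 2L,
                novel_named_new_gene = 1L, novel_merged_within_3kb = 1L,
                novel_retained_unnamed = 3L,
                nonassembled_biotypes_merged = 2L)
  dispositions <- data.frame(
    transfrag_id = c("T_eq", "T_j", "T_short", "T_x", "T_multi", "T_new",
                     "T_merge", "T_far", "T_nohit", "T_intronic"),
    disposition = c("assigned_to_reference_gene", "assigned_to_reference_gene",
                    "dropped_short", "dropped_class_esx", "dropped_multigene",
                    "novel_named_new_gene", "novel_merged_within_3kb",
                    "novel_retained_unnamed", "novel_retained_unnamed",
                    "novel_retained_unnamed"),
    stringsAsFactors = FALSE)
  list(refs = refs, transfrags = transfrags, hits = hits,
       ortholog_names = ortholog_names, nonassembled = nonassembled,
       manifest = manifest, expected_dispositions = dispositions)
}
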