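#' Construct a transcript model
#'
#' A transcript is an exon chain on one chromosome and strand, owned by a
#' gene. Coordinates are 0-based half-open internally; the GTF readers and
#' writers are the only place the 1-based shift happens.
#'
#' @param transcript_id,gene_id Identifiers (unique transcript id).
#' @param chrom Chromosome name.
#' @param strand "+" or "-".
#' @param exons Exon-chain matrix from [exon_chain()].
#' @param biotype Transcript biotype (default "protein_coding").
#' @return A `TranscriptModel` list.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "protein_coding") {
  stopifnot(is.character(transcript_id), nzchar(chrom),
            strand %in% c("+", "-"))
  validate_exons(exons)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype),
            class = "TranscriptModel")
}

#' Construct an assembled transfrag
#'
#' @param transfrag_id Identifier.
#' @param chrom Chromosome.
#' @param strand "+", "-" or "." (unknown; single-exon transfrags only).
#' @param exons Exon-chain matrix.
#' @return A `Transfrag` list.
#' @export
transfrag <- function(transfrag_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-", "."))
  validate_exons(exons)
  if (strand == "." && nrow(exons) > 1L)
    stop("strand '.' is only allowed for single-exon transfrags")
  structure(list(transfrag_id = transfrag_id, chrom = chrom,
                 strand = strand, exons = exons),
            class = "Transfrag")
}

#' Build an annotation set from transcript models
#'
#' Groups transcripts by gene, computes each gene's locus as the span of
#' its transcripts and checks identifier uniqueness.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param gene_names Optional named character vector gene_id -> gene_name.
#' @return An `AnnotationSet` with elements `transcripts` (named list) and
#'   `genes` (data.frame: gene_id, gene_name, chrom, strand, start, end).
#' @export
annotation_set <- function(transcripts = list(), gene_names = character(0)) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  genes <- gene_table(transcripts, gene_names)
  structure(list(transcripts = transcripts, genes = genes),
            class = "AnnotationSet")
}

gene_table <- function(transcripts, gene_names = character(0)) {
  if (length(transcripts) == 0L)
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  rows <- lapply(split(transcripts, gid), function(txs) {
    sp <- vapply(txs, function(t) exon_span(t$exons), integer(2))
    g <- txs[[1L]]$gene_id
    data.frame(gene_id = g,
               gene_name = if (g %in% names(gene_names)) unname(gene_names[g]) else NA_character_,
               chrom = txs[[1L]]$chrom, strand = txs[[1L]]$strand,
               start = min(sp[1L, ]), end = max(sp[2L, ]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$gene_id
  out[order(out$gene_id), , drop = FALSE]
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d genes, %d transcripts\n",
              nrow(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Number of genes / transcripts
#' @param x An `AnnotationSet`.
#' @export
n_genes <- function(x) nrow(x$genes)

#' @rdname n_genes
#' @export
n_transcripts <- function(x) length(x$transcripts)

## Add a transcript to an existing gene, extending its locus if needed.
add_transcript <- function(anno, tx) {
  if (tx$transcript_id %in% names(anno$transcripts))
    stop("transcript_id collision: ", tx$transcript_id)
  if (!tx$gene_id %in% anno$genes$gene_id)
    stop("unknown gene_id: ", tx$gene_id)
  anno$transcripts[[tx$transcript_id]] <- tx
  sp <- exon_span(tx$exons)
  g <- tx$gene_id
  anno$genes[g, "start"] <- min(anno$genes[g, "start"], sp[1L])
  anno$genes[g, "end"] <- max(anno$genes[g, "end"], sp[2L])
  anno
}

## Add a brand-new gene holding one transcript.
add_gene <- function(anno, tx, gene_name = NA_character_) {
  if (tx$gene_id %in% anno$genes$gene_id)
    stop("gene_id collision: ", tx$gene_id)
  sp <- exon_span(tx$exons)
  anno$genes <- rbind(anno$genes,
                      data.frame(gene_id = tx$gene_id, gene_name = gene_name,
                                 chrom = tx$chrom, strand = tx$strand,
                                 start = sp[1L], end = sp[2L],
                                 stringsAsFactors = FALSE))
  rownames(anno$genes) <- anno$genes$gene_id
  anno$transcripts[[tx$transcript_id]] <- tx
  anno
}

#' Read a GTF file into an AnnotationSet
#'
#' Exon features are grouped by `transcript_id`; `gene_id`, `gene_name`
#' and `biotype`/`gene_biotype` attributes are honoured. GTF 1-based
#' inclusive coordinates are shifted to the internal 0-based half-open
#' convention here and nowhere else.
#'
#' @param path GTF file.
#' @return An `AnnotationSet`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   transcript_id = gr$transcript_id,
                   gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  df$biotype <- if ("biotype" %in% names(S4Vectors::mcols(gr))) gr$biotype
                else if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) gr$gene_biotype
                else "protein_coding"
  df$gene_name <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) gr$gene_name
                  else NA_character_
  txs <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], exon_chain(d$start, d$end),
                     biotype = ifelse(is.na(d$biotype[1L]), "protein_coding", d$biotype[1L]))
  })
  gn <- df[!is.na(df$gene_name), c("gene_id", "gene_name")]
  gn <- gn[!duplicated(gn$gene_id), ]
  annotation_set(unname(txs), stats::setNames(gn$gene_name, gn$gene_id))
}

#' Read a GTF file into a list of Transfrags
#'
#' StringTie-style assembled transcripts; strand "*" becomes ".".
#'
#' @param path GTF file.
#' @return List of `Transfrag` objects.
#' @export
read_transfrags_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   transcript_id = gr$transcript_id,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "."
  unname(lapply(split(df, df$transcript_id), function(d) {
    transfrag(d$transcript_id[1L], d$chrom[1L], d$strand[1L],
              exon_chain(d$start, d$end))
  }))
}

#' Write an AnnotationSet to GTF
#'
#' Emits one `transcript` row plus its `exon` rows per transcript, with
#' `gene_id`, `transcript_id`, `gene_name` and `biotype` attributes.
#'
#' @param anno An `AnnotationSet`.
#' @param path Output file.
#' @export
write_gtf <- function(anno, path) {
  txs <- anno$transcripts[order(names(anno$transcripts))]
  rows <- lapply(txs, function(t) {
    sp <- exon_span(t$exons)
    nm <- anno$genes[t$gene_id, "gene_name"]
    data.frame(chrom = t$chrom,
               start = c(sp[1L], t$exons[, 1]) + 1L,
               end = c(sp[2L], t$exons[, 2]),
               strand = t$strand,
               type = c("transcript", rep("exon", nrow(t$exons))),
               gene_id = t$gene_id, transcript_id = t$transcript_id,
               gene_name = if (is.na(nm)) t$gene_id else nm,
               biotype = t$biotype, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type
  gr$gene_id <- df$gene_id
  gr$transcript_id <- df$transcript_id
  gr$gene_name <- df$gene_name
  gr$biotype <- df$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
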