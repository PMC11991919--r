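# helpers building minimal single-gene references on their own chromosome
one_gene <- function(gid, chrom, s, e, strand = "+")
  transcript_model(paste0(gid, "_T"), gid, chrom, strand, exon_chain(s, e))

test_that("filter_transfrags drops short, e/s/x and multi-gene transfrags", {
  refs <- annotation_set(list(
    one_gene("GA", "c1", 1000L, 2000L),
    one_gene("GB", "c2", 1000L, 2000L),
    one_gene("GC1", "c3", 1000L, 2000L), one_gene("GC2", "c3", 3000L, 4000L)))
  tfs <- list(
    transfrag("short1", "c1", "+", exon_chain(1100L, 1250L)),    # 150 bp
    transfrag("keep200", "c1", "+", exon_chain(1000L, 1200L)),   # 200 bp kept
    transfrag("oppx", "c2", "-", exon_chain(1100L, 1400L)),      # 'x'
    transfrag("multi", "c3", "+", exon_chain(1500L, 3500L)))     # two genes
  res <- classify_transfrags(tfs, refs)
  flt <- filter_transfrags(res, tfs)
  expect_setequal(vapply(flt$kept, `[[`, "", "transfrag_id"), "keep200")
  expect_equal(flt$dropped$reason[flt$dropped$transfrag_id == "short1"], "short")
  expect_equal(flt$dropped$reason[flt$dropped$transfrag_id == "oppx"], "class_esx")
  expect_equal(flt$dropped$reason[flt$dropped$transfrag_id == "multi"], "multigene")
})

test_that("a 200 bp transfrag sits on the keep side of the length rule", {
  refs <- annotation_set(list(one_gene("GA", "c1", 1000L, 2000L)))
  tfs <- list(transfrag("t200", "c1", "+", exon_chain(1000L, 1200L)),
              transfrag("t199", "c1", "+", exon_chain(1000L, 1199L)))
  flt <- filter_transfrags(classify_transfrags(tfs, refs), tfs)
  expect_equal(vapply(flt$kept, `[[`, "", "transfrag_id"), "t200")
})

test_that("a planted 12-transfrag filter fixture matches its manifest", {
  # 3 short, 2 code-x, 2 multigene, 5 clean
  refs <- annotation_set(c(
    lapply(1:12, function(i) one_gene(paste0("G", i), paste0("ch", i),
                                      1000L, 2000L)),
    list(one_gene("G13", "ch11", 3000L, 4000L),
         one_gene("G14", "ch12", 3000L, 4000L))))
  mk <- function(id, chrom, s, e, strand = "+")
    transfrag(id, chrom, strand, exon_chain(s, e))
  tfs <- c(lapply(1:3, function(i) mk(paste0("S", i), paste0("ch", i),
                                      1100L, 1100L + 150L)),
           lapply(1:2, function(i) mk(paste0("X", i), paste0("ch", i + 3L),
                                      1100L, 1500L, strand = "-")),
           lapply(1:2, function(i) mk(paste0("M", i), paste0("ch", i + 10L),
                                      1500L, 3500L)),
           lapply(1:5, function(i) mk(paste0("K", i), paste0("ch", i + 5L),
                                      1100L, 1600L)))
  flt <- filter_transfrags(classify_transfrags(tfs, refs), tfs)
  expect_equal(length(flt$kept), 5L)
  expect_setequal(vapply(flt$kept, `[[`, "", "transfrag_id"), paste0("K", 1:5))
  expect_equal(sort(table(flt$dropped$reason)),
               sort(table(c(rep("short", 3), rep("class_esx", 2),
                            rep("multigene", 2)))))
})

test_that("mismatched id sets are an error", {
  refs <- annotation_set(list(one_gene("GA", "c1", 1000L, 2000L)))
  tfs <- list(transfrag("a", "c1", "+", exon_chain(1000L, 1300L)))
  res <- classify_transfrags(tfs, refs)
  res$transfrag_id <- "b"
  expect_error(filter_transfrags(res, tfs), "do not match")
})

test_that("resolve_novel handles the no-hit / new-gene / window branches", {
  refs <- annotation_set(list(one_gene("GENE_F", "c1", 10000L, 20000L)))
  t_near <- transfrag("tn", "c1", "+", exon_chain(20500L, 21000L))
  t_far <- transfrag("tf", "c1", "+", exon_chain(23500L, 24000L))
  hit <- data.frame(query_id = "tn", subject_transcript_id = "HS1",
                    subject_gene_name = "SOX2", subject_species = "human",
                    evalue = 1e-30, bitscore = 300, pct_identity = 95,
                    stringsAsFactors = FALSE)

  expect_equal(resolve_novel(t_near, "u", NULL, refs, character(0))$disposition,
               "novel_retained_unnamed")
  # SOX2 absent from the annotation: founded as a new gene of that name
  r <- resolve_novel(t_near, "u", hit, refs, character(0))
  expect_equal(r$disposition, "novel_named_new_gene")
  expect_equal(r$gene_id, "SOX2")
  # known ortholog with an annotation entry: window arithmetic decides
  hitF <- transform(hit, subject_gene_name = "TBX3")
  orth <- c(TBX3 = "GENE_F")
  expect_equal(resolve_novel(t_near, "u", hitF, refs, orth)$disposition,
               "novel_merged_within_3kb")
  expect_equal(resolve_novel(t_far, "u", hitF, refs, orth)$disposition,
               "novel_retained_unnamed")
})

test_that("hits above the e-value threshold are rejected", {
  refs <- annotation_set(list(one_gene("GENE_F", "c1", 10000L, 20000L)))
  t <- transfrag("tn", "c1", "+", exon_chain(20500L, 21000L))
  bad <- data.frame(query_id = "tn", subject_transcript_id = "HS1",
                    subject_gene_name = "SOX2", subject_species = "human",
                    evalue = 1e-10, bitscore = 50, pct_identity = 80,
                    stringsAsFactors = FALSE)
  expect_error(resolve_novel(t, "u", bad, refs, character(0)), "e-value")
})

test_that("reconcile with no transfrags is the union of refs and nonassembled", {
  fx <- make_reconcile_fixture()
  rc <- reconcile(fx$refs, list(), nonassembled = fx$nonassembled)
  expect_equal(unname(rc$report["nonassembled_biotypes_merged"]), 2L)
  expect_equal(sum(rc$report[1:7]), 0L)
  expect_equal(n_genes(rc$annotation), n_genes(fx$refs) + 2L)
  expect_true(all(fx$refs$genes$gene_id %in% rc$annotation$genes$gene_id))
})

test_that("the planted disposition fixture reproduces its manifest exactly", {
  fx <- make_reconcile_fixture()
  rc <- reconcile(fx$refs, fx$transfrags, fx$hits, fx$nonassembled,
                  fx$ortholog_names)
  expect_identical(rc$report, fx$manifest)
  got <- rc$dispositions[match(fx$expected_dispositions$transfrag_id,
                               rc$dispositions$transfrag_id), ]
  expect_equal(got$disposition, fx$expected_dispositions$disposition)
  # every input transfrag lands in exactly one disposition
  expect_setequal(rc$dispositions$transfrag_id,
                  vapply(fx$transfrags, `[[`, "", "transfrag_id"))
  # conservation: all reference genes survive
  expect_true(all(fx$refs$genes$gene_id %in% rc$annotation$genes$gene_id))
  # the SOX2 gene was founded by the planted hit
  expect_true("SOX2" %in% rc$annotation$genes$gene_id)
})

test_that("an '=' transfrag inside its gene locus leaves the locus unchanged", {
  refs <- ref_locus <- annotation_set(list(transcript_model(
    "R1", "G1", "c1", "+",
    exon_chain(c(1000L, 1500L), c(1200L, 1700L)))))
  t <- transfrag("tfx", "c1", "+", exon_chain(c(1050L, 1500L), c(1200L, 1650L)))
  rc <- reconcile(refs, list(t))
  expect_equal(unname(rc$report["assigned_to_reference_gene"]), 1L)
  expect_equal(length(rc$annotation$genes$gene_id), 1L)
  expect_equal(rc$annotation$genes["G1", c("start", "end")],
               refs$genes["G1", c("start", "end")])
  expect_equal(n_transcripts(rc$annotation), 2L)
})

test_that("transcript id collisions with the reference are renamed", {
  refs <- annotation_set(list(one_gene("GA", "c1", 1000L, 2000L)))
  t <- transfrag("GA_T", "c1", "+", exon_chain(1000L, 2000L))  # same id
  rc <- reconcile(refs, list(t))
  expect_true("GA_T_1" %in% names(rc$annotation$transcripts))
})

test_that("a reconciled annotation round-trips through GTF", {
  fx <- make_reconcile_fixture()
  rc <- reconcile(fx$refs, fx$transfrags, fx$hits, fx$nonassembled,
                  fx$ortholog_names)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(rc$annotation, path)
  back <- read_gtf(path)
  expect_setequal(names(back$transcripts), names(rc$annotation$transcripts))
  for (id in names(rc$annotation$transcripts)) {
    a <- rc$annotation$transcripts[[id]]; b <- back$transcripts[[id]]
    expect_identical(unname(a$exons), unname(b$exons))
    expect_identical(a[c("gene_id", "chrom", "strand")],
                     b[c("gene_id", "chrom", "strand")])
  }
  g <- rc$annotation$genes[order(rownames(rc$annotation$genes)), ]
  expect_equal(back$genes[rownames(g), c("chrom", "strand", "start", "end")],
               g[, c("chrom", "strand", "start", "end")])
})

test_that("blast tabular reading keeps one best hit per query", {
  hits_path <- withr::local_tempfile(fileext = ".tsv")
  sub_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95\t500\t10\t1\t1\t500\t1\t500\t1e-50\t400",
               "q1\ts2\t90\t480\t20\t2\t1\t480\t1\t480\t1e-40\t350",
               "q2\ts3\t99\t300\t1\t0\t1\t300\t1\t300\t1e-80\t600"),
             hits_path)
  writeLines(c("subject_id\tgene_name\tspecies",
               "s1\tSOX2\thuman", "s2\tSOX2\tmouse", "s3\tGATA3\thuman"),
             sub_path)
  h <- read_blast_hits(hits_path, sub_path)
  expect_equal(nrow(h), 2L)
  expect_equal(h$subject_transcript_id[h$query_id == "q1"], "s1")
  expect_equal(h$subject_gene_name[h$query_id == "q2"], "GATA3")
})
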