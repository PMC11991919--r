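test_that("ortholog alignment keeps one2one pairs only", {
  a <- matrix(1, 4, 2, dimnames = list(c("a1", "a2", "a3", "a4"), c("x", "y")))
  b <- matrix(1, 4, 2, dimnames = list(c("b1", "b2", "b3", "b4"), c("u", "v")))
  ot <- data.frame(gene_a = c("a1", "a2", "a3"),
                   gene_b = c("b1", "b2", "b3"),
                   homology_type = c("ortholog_one2one", "ortholog_one2many",
                                     "ortholog_one2one"))
  al <- align_orthologs(a, b, ot)
  expect_equal(nrow(al$a), 2L)
  expect_equal(al$map$gene_a, c("a1", "a3"))
  expect_identical(rownames(al$a), rownames(al$b))
  expect_error(align_orthologs(a, b, ot[2, ]), "no one2one")
})

test_that("symbol fallback pairs unmapped genes of identical name", {
  a <- matrix(1, 3, 2, dimnames = list(c("a1", "SOX2", "NANOG"), c("x", "y")))
  b <- matrix(1, 3, 2, dimnames = list(c("b1", "SOX2", "NANOG"), c("u", "v")))
  ot <- data.frame(gene_a = "a1", gene_b = "b1",
                   homology_type = "ortholog_one2one")
  expect_equal(nrow(align_orthologs(a, b, ot)$a), 1L)
  al <- align_orthologs(a, b, ot, symbol_fallback = TRUE)
  expect_equal(nrow(al$a), 3L)
  expect_true(all(c("NANOG|NANOG", "SOX2|SOX2") %in% al$map$ortholog_key))
})

test_that("a planted 100-gene table with 80 one2one yields 80 shared rows", {
  genes_a <- sprintf("ha%03d", 1:100)
  genes_b <- sprintf("mb%03d", 1:100)
  a <- matrix(rpois(300, 4), 100, 3, dimnames = list(genes_a, paste0("x", 1:3)))
  b <- matrix(rpois(300, 4), 100, 3, dimnames = list(genes_b, paste0("y", 1:3)))
  ot <- data.frame(gene_a = genes_a, gene_b = genes_b,
                   homology_type = rep(c("ortholog_one2one", "ortholog_one2many"),
                                       c(80, 20)))
  al <- align_orthologs(a, b, ot)
  expect_equal(nrow(al$a), 80L)
  expect_equal(nrow(al$map), 80L)
})

test_that("lineage assignment follows argmax, the 10% rule and tie order", {
  pb <- rbind(epi_only = c(EPI = 5, PE = 0, TE = 0),
              low_te = c(EPI = 1, PE = 1, TE = 4),
              tie = c(EPI = 2, PE = 2, TE = 1),
              zero = c(EPI = 0, PE = 0, TE = 0))
  pct <- rbind(epi_only = c(EPI = 0.9, PE = 0, TE = 0),
               low_te = c(EPI = 0.5, PE = 0.5, TE = 0.08),
               tie = c(EPI = 0.8, PE = 0.9, TE = 0.2),
               zero = c(EPI = 0, PE = 0, TE = 0))
  al <- assign_lineage(pb, pct)
  expect_equal(al$lineage[al$gene_id == "epi_only"], "EPI")
  # highest mean in TE but detected in only 8% of TE cells
  expect_equal(al$lineage[al$gene_id == "low_te"], "unexpressed")
  # exact tie resolved by the fixed lineage order, flagged
  expect_equal(al$lineage[al$gene_id == "tie"], "EPI")
  expect_true(al$tied[al$gene_id == "tie"])
  expect_equal(al$lineage[al$gene_id == "zero"], "unexpressed")
})

test_that("planted argmax designs are recovered in full", {
  set.seed(14)
  lins <- c("EPI", "PE", "TE")
  truth <- sample(lins, 200, replace = TRUE)
  pb <- matrix(1, 200, 3, dimnames = list(sprintf("g%03d", 1:200), lins))
  pct <- matrix(0.9, 200, 3, dimnames = dimnames(pb))
  for (i in 1:200) pb[i, truth[i]] <- 6
  al <- assign_lineage(pb, pct)
  expect_equal(al$lineage, truth[match(al$gene_id, rownames(pb))])
})

test_that("conservation categories match an exhaustive hand enumeration", {
  states <- c("EPI", "TE", "unexpressed")
  grid <- expand.grid(h = states, m = states, g = states,
                      stringsAsFactors = FALSE)
  keys <- sprintf("k%02d", seq_len(nrow(grid)))
  asg <- list(human = stats::setNames(grid$h, keys),
              mouse = stats::setNames(grid$m, keys),
              gp = stats::setNames(grid$g, keys))
  got <- classify_conservation(asg)
  # literal transcription of the rule, case by case
  expected <- mapply(function(h, m, g) {
    if (h != "unexpressed" && h == m && m == g) "all_three"
    else if (h != "unexpressed" && h == g) "human_gp_only"
    else if (m != "unexpressed" && m == g) "mouse_gp_only"
    else if (h != "unexpressed" && h == m) "human_mouse_only"
    else "none"
  }, grid$h, grid$m, grid$g, USE.NAMES = FALSE)
  expect_equal(got$records$category[match(keys, got$records$ortholog_key)],
               expected)
  # partition: every key in exactly one category, counts sum to total
  expect_equal(sum(got$counts), nrow(grid))
})

test_that("a species missing a key is treated as unexpressed there", {
  asg <- list(human = c(k1 = "EPI"), mouse = c(k2 = "TE"),
              gp = c(k1 = "EPI", k2 = "TE"))
  got <- classify_conservation(asg)
  expect_equal(got$records$category[got$records$ortholog_key == "k1"],
               "human_gp_only")
  expect_equal(got$records$category[got$records$ortholog_key == "k2"],
               "mouse_gp_only")
})

test_that("noiseless planted conservation design is recovered exactly", {
  sim <- simulate_counts(conservation_design(n_per_category = 10L,
                                             dispersion = 0, depth_sd = 0,
                                             seed = 3L))
  asg <- lapply(sim$species, function(sp) {
    nm <- log_normalize(filter_genes(sp$counts, 3L))
    groups <- sp$meta$lineage[match(colnames(nm), sp$meta$cell_id)]
    al <- assign_lineage(pseudo_bulk(nm, groups),
                         detection_fraction(nm, groups))
    stats::setNames(al$lineage, sub("^[a-z]+_", "", al$gene_id))
  })
  truth <- sim$manifest$conserved
  asg <- lapply(asg, function(a) a[names(a) %in% truth$gene])
  got <- classify_conservation(asg)
  expect_equal(got$records$category[match(truth$gene, got$records$ortholog_key)],
               truth$category)
})
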