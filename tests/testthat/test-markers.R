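norm_mat <- function(values, nr, nc)
  matrix(values, nr, nc, dimnames = list(sprintf("g%03d", seq_len(nr)),
                                         paste0("c", seq_len(nc))))

test_that("log2 fold change follows its closed form and is monotone", {
  expect_equal(log2_fold_change(c(1, 2), c(1, 2)), 0)
  # de-logged in-group mean 3, out-group mean 1 -> log2(4/2) = 1
  expect_equal(log2_fold_change(rep(log(4), 5), rep(log(2), 5)), 1)
  base <- log2_fold_change(c(1, 2, 3), c(1, 1))
  expect_gte(log2_fold_change(c(1, 2, 4), c(1, 1)), base)
})

test_that("genes identical across groups are never reported", {
  set.seed(8)
  counts <- matrix(rnbinom(100 * 40, size = 2, mu = 5), 100, 40,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:40)))
  nm <- log_normalize(counts)
  groups <- rep(c("A", "B"), each = 20)
  mk <- find_markers(nm, groups, contrast = c("A", "B"))
  # same NB law in both groups: nothing should clear Bonferroni
  expect_equal(nrow(mk), 0L)
})

test_that("each threshold is enforced individually", {
  # 60 cells, two groups; g001 is a strong true marker, g002 has a solid
  # p but a fold change below threshold, g003 is detected in <= 10% of
  # cells in both groups
  set.seed(21)
  nA <- 30L; nB <- 30L
  counts <- matrix(rnbinom(50 * 60, size = 2, mu = 5), 50, 60,
                   dimnames = list(sprintf("g%03d", 1:50), paste0("c", 1:60)))
  counts["g001", 1:30] <- rnbinom(30, size = 2, mu = 60)
  counts["g002", 1:30] <- counts["g002", 31:60] + 1L   # tiny uniform shift
  counts["g003", ] <- 0L
  counts["g003", c(1, 2, 31, 32)] <- 100L              # 2/30 cells per group
  nm <- log_normalize(counts)
  groups <- rep(c("A", "B"), c(nA, nB))
  mk <- find_markers(nm, groups, contrast = c("A", "B"))
  expect_true("g001" %in% mk$gene_id)
  expect_false("g002" %in% mk$gene_id)   # log2FC below 0.25
  expect_false("g003" %in% mk$gene_id)   # pct at most 10% in both groups
})

test_that("one-vs-rest reports positive markers only; pairwise reports both signs", {
  set.seed(5)
  counts <- matrix(rnbinom(30 * 60, size = 2, mu = 5), 30, 60,
                   dimnames = list(sprintf("g%03d", 1:30), paste0("c", 1:60)))
  counts["g001", 1:30] <- rnbinom(30, size = 2, mu = 80)  # up in A
  counts["g002", 31:60] <- rnbinom(30, size = 2, mu = 80) # up in B
  nm <- log_normalize(counts)
  groups <- rep(c("A", "B"), each = 30)
  ovr <- find_markers(nm, groups)
  expect_true(all(ovr$log2fc > 0.25))
  pair <- find_markers(nm, groups, contrast = c("A", "B"))
  expect_true(any(pair$log2fc > 0) && any(pair$log2fc < 0))
  expect_setequal(pair$gene_id[abs(pair$log2fc) > 1], c("g001", "g002"))
})

test_that("Bonferroni adjustment is monotone in the gene universe", {
  set.seed(9)
  counts <- matrix(rnbinom(40 * 30, size = 2, mu = 5), 40, 30,
                   dimnames = list(sprintf("g%03d", 1:40), paste0("c", 1:30)))
  counts["g001", 1:15] <- rnbinom(15, size = 2, mu = 100)
  groups <- rep(c("A", "B"), each = 15)
  small <- find_markers(log_normalize(counts), groups, contrast = c("A", "B"))
  bigger <- rbind(counts,
                  matrix(rnbinom(60 * 30, size = 2, mu = 5), 60, 30,
                         dimnames = list(sprintf("x%03d", 1:60), colnames(counts))))
  big <- find_markers(log_normalize(bigger), groups, contrast = c("A", "B"))
  shared <- intersect(small$gene_id, big$gene_id)
  expect_true(length(shared) > 0)
  expect_true(all(big$p_adj[match(shared, big$gene_id)] >=
                  small$p_adj[match(shared, small$gene_id)] - 1e-12))
})

test_that("groups with fewer than two cells are refused by name", {
  nm <- norm_mat(1, 5, 3)
  expect_error(find_markers(nm, c("A", "A", "B")), "B")
})

test_that("pseudo-bulk averages de-logged values and ignores cell order", {
  nm <- norm_mat(0, 2, 3)
  nm[1, ] <- log(c(3, 5, 2))     # de-logged: 2, 4, 1
  groups <- c("A", "A", "B")
  pb <- pseudo_bulk(nm, groups)
  expect_equal(pb["g001", "A"], 3)      # mean of 2 and 4
  expect_equal(pb["g001", "B"], 1)      # single-cell group: its own value
  perm <- sample(ncol(nm))
  pb2 <- pseudo_bulk(nm[, perm, drop = FALSE], groups[perm])
  expect_equal(pb2, pb)
})
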