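# Risk-gene pruning, high-confidence filtering, specificity groups.

toy_assoc <- function(genes, scores, disease = "AMD") {
  association_table(data.frame(gene = genes, disease_id = disease, score = scores))
}

test_that("pruning applies coding, exclusion and bottom-quantile filters in order", {
  ids <- sprintf("G%02d", 1:20)
  u <- toy_universe(ids)
  # 20 genes, distinct scores 0.01..0.20, 2 excluded, drop 5%
  assoc <- toy_assoc(ids, seq(0.01, 0.20, by = 0.01))
  pruned <- prune_risk_genes(assoc, u, exclusions = list(x = c("G01", "G02")),
    drop_frac = 0.05)
  # floor(0.05 * 18) = 0 dropped at the quantile step; 18 survive
  expect_equal(nrow(pruned), 18L)
  expect_false(any(c("G01", "G02") %in% pruned$gene_id))
  # identity with no exclusions and drop 0
  expect_equal(nrow(prune_risk_genes(assoc, u, drop_frac = 0)), 20L)
  # non-coding (unresolvable) names are removed first
  assoc2 <- toy_assoc(c(ids, "NOTAGENE"), c(seq(0.01, 0.20, by = 0.01), 0.9))
  p2 <- prune_risk_genes(assoc2, u, drop_frac = 0)
  expect_equal(nrow(p2), 20L)
  expect_identical(attr(p2, "unmapped"), "NOTAGENE")
  expect_error(prune_risk_genes(assoc, u, drop_frac = 1), "drop_frac")
})

test_that("the quantile step runs on the post-exclusion list (order matters)", {
  ids <- sprintf("G%02d", 1:40)
  u <- toy_universe(ids)
  assoc <- toy_assoc(ids, seq(0.01, 0.40, by = 0.01))
  excl <- list(x = ids[1:20])  # excludes exactly the low-score half
  pruned <- prune_risk_genes(assoc, u, exclusions = excl, drop_frac = 0.1)
  # post-exclusion n = 20, floor(2) = 2 more dropped: G21, G22
  expect_equal(nrow(pruned), 18L)
  expect_false(any(c("G21", "G22") %in% pruned$gene_id))
  # quantile-first would instead have dropped floor(0.1 * 40) = 4 low scorers
  # before exclusions and left 20 - 0 = 16 genes; assert the difference
  n_drop_first <- length(setdiff(ids[-(1:4)], excl$x))
  expect_false(n_drop_first == nrow(pruned))
})

test_that("a gene reached by several raw names keeps its maximum score", {
  u <- toy_universe(c("G1", "G2"), aliases = c("A1", ""))
  assoc <- toy_assoc(c("G1", "A1", "G2"), c(0.3, 0.8, 0.5))
  pruned <- prune_risk_genes(assoc, u, drop_frac = 0)
  expect_equal(pruned$score[pruned$gene_id == "G1"], 0.8)
  expect_equal(nrow(pruned), 2L)
})

test_that("high-confidence filter keeps best classes A-C", {
  pruned <- data.frame(gene_id = paste0("G", 1:5), score = seq(0.9, 0.5, by = -0.1))
  best <- c(G1 = "A", G2 = "B", G3 = "C", G4 = "D", G5 = "F")
  hc <- filter_high_confidence(pruned, best)
  expect_identical(hc$gene_id, c("G1", "G2", "G3"))
  # allowing everything is the identity
  expect_equal(nrow(filter_high_confidence(pruned, best, allowed = EXPRESSION_GROUPS)), 5L)
})

test_that("specificity groups follow the tier-and-overlap rule table", {
  ids <- paste0("G", 1:6)
  u <- toy_universe(ids, tissue = c(
    "Detected in single", "Detected in some", "Detected in some",
    "Detected in many", "Detected in all", "Detected in all"
  ))
  age <- list(S1 = c("G2", "G4", "G6"))
  grp <- assign_specificity_groups(ids, u, age)
  expect_identical(unname(grp), c("1a", "1b", "1a", "2", "3", "3"))
  # groups partition the list
  expect_equal(sum(table(grp)), 6L)
  # all "Detected in all" -> all group 3
  u3 <- toy_universe(ids, tissue = rep("Detected in all", 6))
  expect_true(all(assign_specificity_groups(ids, u3, age) == "3"))
  # a gene outside the universe is an error
  expect_error(assign_specificity_groups("NOPE", u, age), "missing from the universe")
})

test_that("adding a gene to an age set can only move it 1a -> 1b", {
  ids <- paste0("G", 1:4)
  u <- toy_universe(ids, tissue = c(
    "Detected in some", "Detected in many", "Detected in all", "Detected in single"
  ))
  before <- assign_specificity_groups(ids, u, list())
  after <- assign_specificity_groups(ids, u, list(S = ids))
  expect_identical(unname(before), c("1a", "2", "3", "1a"))
  expect_identical(unname(after), c("1b", "2", "3", "1b"))
})

test_that("disease overlap counts, fraction and ranking are correct", {
  ids <- paste0("g", 1:4)
  u <- toy_universe(ids)
  s <- disease_overlap_summary(ids, u, list(S1 = c("g1", "g2"), S2 = "g1"))
  expect_equal(unname(s$counts[ids]), c(2L, 1L, 0L, 0L))
  expect_equal(s$overlap_fraction, 0.5)
  expect_identical(s$ranking$gene_id[1:2], c("g1", "g2"))
  # empty collection: all zero
  s0 <- disease_overlap_summary(ids, u, list())
  expect_true(all(s0$counts == 0))
  expect_equal(s0$overlap_fraction, 0)
})

test_that("risk records mark specificity only for high-confidence genes", {
  ids <- paste0("G", 1:3)
  u <- toy_universe(ids, tissue = rep("Detected in some", 3))
  pruned <- data.frame(gene_id = ids, score = c(0.9, 0.8, 0.7))
  best <- c(G1 = "A", G2 = "D", G3 = "B")
  rec <- risk_gene_records(pruned, best, u, age_sets = list(S = "G3"))
  expect_identical(rec$specificity_group, c("1a", NA, "1b"))
  expect_equal(rec$n_other_diseases, c(0L, 0L, 1L))
})
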