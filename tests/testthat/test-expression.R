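# Expression grouping, best groups, specificity z-scores.

test_that("20 distinct values cut into the documented group sizes", {
  ids <- sprintf("G%02d", 1:20)
  u <- toy_universe(ids)
  m <- toy_matrix(20:1, ids, "ct1")
  tab <- assign_expression_groups(m, u, grouping_policy(universe_size = 20))
  g <- tab$groups[, "ct1"]
  # quota = round_half_up(0.01 * 20) = 0: no A, then 5/10/5 for B/C/D
  expect_identical(unname(g[ids[1:5]]), rep("B", 5))
  expect_identical(unname(g[ids[6:15]]), rep("C", 10))
  expect_identical(unname(g[ids[16:20]]), rep("D", 5))
  expect_identical(
    g, oracle_groups(20:1, ids, universe_size = 20)[names(g)]
  )
})

test_that("an all-zero cell type yields no A-D, all present genes E", {
  ids <- paste0("G", 1:10)
  u <- toy_universe(ids)
  m <- toy_matrix(rep(0, 10), ids, "ct1")
  tab <- assign_expression_groups(m, u, grouping_policy(universe_size = 10))
  expect_identical(unname(tab$groups[, "ct1"]), rep("E", 10))
})

test_that("groups partition present genes and match the oracle on random instances", {
  set.seed(101)
  for (rep_i in 1:40) {
    n <- sample(30:300, 1)
    ids <- sprintf("G%04d", seq_len(n))
    n_present <- sample(seq(10, n), 1)
    present <- sort(sample(ids, n_present))
    vals <- round(rlnorm(n_present), 3)
    vals[runif(n_present) < 0.2] <- 0
    u <- toy_universe(ids)
    m <- toy_matrix(vals, present, "ct1")
    tab <- assign_expression_groups(m, u, grouping_policy(universe_size = n))
    g <- tab$groups[, "ct1"]
    # partition: A-E cover exactly the present genes, F the rest
    expect_equal(sum(g != "F"), n_present)
    expect_identical(sort(names(g)[g != "F"]), present)
    # oracle equivalence
    exp_g <- oracle_groups(vals, present, universe_size = n)
    expect_identical(unname(g[present]), unname(exp_g[present]))
    # B:C:D within 1 of 25:50:25 of the expressed remainder
    rem <- sum(vals > 0) - sum(g == "A")
    expect_lte(abs(sum(g == "B") - 0.25 * rem), 1)
    expect_lte(abs(sum(g == "C") - 0.50 * rem), 1)
    expect_lte(abs(sum(g == "D") - 0.25 * rem), 1)
  }
})

test_that("raising a gene's expression never demotes its group", {
  set.seed(7)
  ids <- sprintf("G%03d", 1:60)
  u <- toy_universe(ids)
  vals <- round(rlnorm(60), 3)
  ord <- c("A", "B", "C", "D", "E", "F")
  for (i in c(1, 25, 60)) {
    v2 <- vals
    v2[i] <- vals[i] * 3 + 1
    g1 <- assign_expression_groups(toy_matrix(vals, ids, "ct"), u,
      grouping_policy(universe_size = 60))$groups[i, "ct"]
    g2 <- assign_expression_groups(toy_matrix(v2, ids, "ct"), u,
      grouping_policy(universe_size = 60))$groups[i, "ct"]
    expect_lte(match(g2, ord), match(g1, ord))
  }
})

test_that("tie-break at cut boundaries is by expression then gene id", {
  ids <- c("G1", "G2", "G3", "G4")
  u <- toy_universe(ids)
  # all equal: ordering falls back to gene id; cuts 1/2/1 for B/C/D
  m <- toy_matrix(rep(5, 4), ids, "ct")
  g <- assign_expression_groups(m, u, grouping_policy(universe_size = 4))$groups[, "ct"]
  expect_identical(unname(g), c("B", "C", "C", "D"))
})

test_that("best group is the minimum over all cell types of all datasets", {
  ids <- c("G1", "G2", "G3")
  u <- toy_universe(ids)
  t1 <- assign_expression_groups(
    toy_matrix(c(9, 1, 0), ids, c("ct1"), dataset = "choroid_rpe"),
    u, grouping_policy(universe_size = 3))
  t2 <- assign_expression_groups(
    toy_matrix(c(4, 8), c("G1", "G2"), c("ct2"), dataset = "nr"),
    u, grouping_policy(universe_size = 3))
  best <- best_group(list(t1, t2))
  # toy ordering check: G2 is {ct1: C, ct2: B} -> B
  expect_identical(unname(best["G2"]), "B")
  # G1 is {ct1: B, ct2: C} -> B
  expect_identical(unname(best["G1"]), "B")
  # absent from every dataset -> F
  t3 <- assign_expression_groups(
    toy_matrix(c(1, 1), c("G1", "G2"), "ct3", dataset = "x"),
    u, grouping_policy(universe_size = 3))
  expect_identical(unname(best_group(t3)["G3"]), "F")
})

test_that("best group picks A over E across cell types when the quota admits it", {
  ids <- sprintf("G%03d", 1:100)
  u <- toy_universe(ids)
  vals <- cbind(c(100, rep(0, 99)), rep(1, 100))
  m <- expression_matrix(matrix(vals, 100, 2, dimnames = list(ids, c("c1", "c2"))), "d")
  tab <- assign_expression_groups(m, u, grouping_policy(universe_size = 100))
  expect_identical(unname(tab$groups["G001", "c1"]), "A")  # quota 1
  expect_identical(unname(best_group(tab)["G001"]), "A")
})

test_that("z-scores standardize each gene across cell types", {
  ids <- c("G1", "G2", "G3")
  m <- toy_matrix(c(1, 4, 0, 2, 4, 0, 3, 4, 0), ids, c("c1", "c2", "c3"))
  z <- compute_zscores(m)
  # worked case: (1,2,3) -> (-1, 0, 1) with the sample sd
  expect_equal(unname(z["G1", ]), c(-1, 0, 1))
  # constant row -> all NA
  expect_true(all(is.na(z["G2", ])))
  expect_true(all(is.na(z["G3", ])))
  # a data point equal to the mean scores 0
  expect_equal(unname(z["G1", "c2"]), 0)
  # defined rows have mean 0 and sample sd 1
  expect_lt(abs(mean(z["G1", ])), 1e-9)
  expect_lt(abs(sd(z["G1", ]) - 1), 1e-9)
  expect_error(compute_zscores(toy_matrix(1:3, ids, "only")), "single-cell-type")
})

test_that("z-flags use an inclusive threshold and ignore NA rows", {
  ids <- c("G1", "G2")
  # one-hot over 7 cell types: z in the hot cell is (n-1)/sqrt(n) = 6/sqrt(7)
  vals <- matrix(rep(c(0, 5), 7), nrow = 2, dimnames = list(ids, paste0("c", 1:7)))
  vals["G1", "c7"] <- 10
  z <- compute_zscores(expression_matrix(vals, "d"))
  expect_equal(unname(z["G1", "c7"]), 6 / sqrt(7))
  fl <- flag_specific(z, threshold = 2.0)
  expect_identical(unname(fl["G1", ]), c(rep(FALSE, 6), TRUE))
  expect_false(any(fl["G2", ]))  # constant -> NA -> never flagged
  # an exact z == threshold is flagged (inclusive bound)
  fl2 <- flag_specific(z, threshold = 6 / sqrt(7))
  expect_true(fl2["G1", "c7"])
  # the (1,2,3) worked case never reaches 2
  z2 <- compute_zscores(toy_matrix(c(1, 2, 3), "G1", paste0("c", 1:3)))
  expect_false(any(flag_specific(z2)))
})
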