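# Generator determinism, planted ground truth, statistical contracts.

test_that("the same seed yields byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_bundle(small_config(seed = 5), d1)
  generate_bundle(small_config(seed = 5), d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_bundle(small_config(seed = 6), d3)
  expect_false(identical(
    readLines(file.path(d1, "expr_nr.tsv")),
    readLines(file.path(d3, "expr_nr.tsv"))
  ))
})

test_that("zero-inflation matches its nominal rate within binomial noise", {
  cfg <- synthetic_config(seed = 3, n_genes = 10000, zero_frac = 0.3,
    n_risk = 50, n_seeds = 5, interactors_per_seed = 3,
    background_nodes = 100, background_edges = 100,
    age_set_size = 50, exclusion_set_size = 10, exclusion_risk_overlap = 5)
  gen <- generate_bundle(cfg, withr::local_tempdir())
  m <- read_expression_matrix(gen$paths$expr_nr, "nr")
  n_cells <- length(m$values)
  obs <- mean(m$values == 0)
  tol <- 3 * sqrt(0.3 * 0.7 / n_cells)
  expect_lt(abs(obs - 0.3), tol)
})

test_that("forced-top planting makes exactly the planted genes class A", {
  gen <- generate_bundle(small_config(), withr::local_tempdir())
  b <- load_bundle(gen$paths$bundle)
  tab <- assign_expression_groups(b$matrices$choroid_rpe, b$universe,
    grouping_policy(universe_size = nrow(b$universe)))
  ct <- gen$config$top_cell
  a_genes <- sort(rownames(tab$groups)[tab$groups[, ct] == "A"])
  expect_identical(a_genes, sort(gen$manifest$planted$class_a$genes))
  expect_length(a_genes, gen$manifest$quota)
})

test_that("every generated bundle passes load validation with matching counts", {
  gen <- generate_bundle(small_config(seed = 77), withr::local_tempdir())
  b <- load_bundle(gen$paths$bundle)
  expect_s3_class(b, "rcc_bundle")
  expect_equal(nrow(b$universe), gen$manifest$row_counts$universe)
  expect_equal(nrow(b$ppi), gen$manifest$row_counts$ppi_edges)
  expect_equal(
    unname(vapply(b$matrices, function(m) nrow(m$values), integer(1))),
    unname(unlist(gen$manifest$row_counts[c("expr_choroid_rpe", "expr_nr")]))
  )
})

test_that("an infeasible planted configuration errors", {
  expect_error(
    synthetic_config(n_genes = 100, n_risk = 80, background_nodes = 50),
    "larger than the universe"
  )
  expect_error(synthetic_config(zero_frac = 1.3), "probabilities")
})

test_that("planted enrichment hits its expected count and tops the ranking", {
  gen <- generate_bundle(small_config(seed = 21), withr::local_tempdir())
  b <- load_bundle(gen$paths$bundle)
  truth <- gen$manifest$planted$enrichment
  risk <- gen$manifest$planted$risk_genes
  # realized in-target class count is near its planted expectation
  se <- sqrt(truth$expected_k * (1 - truth$p1))
  expect_lt(abs(truth$k - truth$expected_k), 4 * se + 1)
  res <- fisher_enrichment(risk, b$universe, level = "sysgo_set2")
  expect_identical(res$class[1], truth$class)
  expect_lt(res$q[1], 0.05)
})

test_that("pipeline recovery on a planted bundle matches the manifest", {
  gen <- generate_bundle(small_config(seed = 13), withr::local_tempdir())
  b <- load_bundle(gen$paths$bundle)
  tabs <- lapply(b$matrices, assign_expression_groups, universe = b$universe,
    policy = grouping_policy(universe_size = nrow(b$universe)))
  best <- best_group(tabs)
  pruned <- prune_risk_genes(b$associations, b$universe, b$exclusions,
    drop_frac = b$policies$drop_frac)
  rec <- risk_gene_records(pruned, best, b$universe, b$age_sets)
  hc <- rec[!is.na(rec$specificity_group), ]
  truth <- unlist(gen$manifest$planted$specificity_groups)
  # recovered specificity labels equal the planted truth, gene by gene
  expect_identical(
    unname(truth[hc$gene_id]),
    hc$specificity_group
  )
  # planted seeds come out as network seeds
  seeds <- select_seed_genes(rec)
  expect_true(all(gen$manifest$planted$seeds %in% seeds))
  # planted interactors pass the first-shell + interactor filters
  for (s in gen$manifest$planted$seeds[1:3]) {
    shell <- extract_first_shell(b$ppi, s)
    kept <- filter_interactors(shell$neighbors, best, b$universe)
    expect_true(all(gen$manifest$planted$interactors_by_seed[[s]] %in% kept))
  }
})
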