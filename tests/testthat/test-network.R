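# Seed selection, first shell, interactor filters, compartment pruning,
# layer assignment, export.

toy_ppi <- function() {
  # 5 edges around SEED: 2 below confidence 0.5, 1 wrong channel,
  # 2 qualifying (one at exactly 0.5)
  ppi_edge_table(data.frame(
    protein_a = rep("SEED", 5),
    protein_b = paste0("N", 1:5),
    confidence = c(0.9, 0.5, 0.49, 0.2, 0.8),
    channels = c("experiments", "databases", "experiments", "databases", "other"),
    stringsAsFactors = FALSE
  ))
}

test_that("seed selection keeps group-1a genes with best class A/B", {
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    score = c(0.9, 0.8, 0.7),
    best_group = c("A", "C", "A"),
    specificity_group = c("1a", "1a", "3"),
    n_other_diseases = 0L, stringsAsFactors = FALSE
  )
  class(rec) <- c("RiskGeneTable", "data.frame")
  expect_identical(select_seed_genes(rec), "g1")
  rec$specificity_group <- c("3", "3", "3")
  expect_identical(select_seed_genes(rec), character(0))
})

test_that("first shell filters by confidence (inclusive) and channel", {
  shell <- extract_first_shell(toy_ppi(), "SEED")
  # N1 (0.9 experiments) and N2 (exactly 0.5 databases) qualify
  expect_identical(shell$neighbors, c("N1", "N2"))
  expect_equal(nrow(shell$edges), 2L)
  # absent seed: warning and empty shell
  expect_warning(empty <- extract_first_shell(toy_ppi(), "GHOST"), "absent")
  expect_length(empty$neighbors, 0)
})

test_that("interactor filter requires high expression and non-ubiquity", {
  nb <- paste0("N", 1:6)
  u <- toy_universe(nb, tissue = c(
    "Detected in some", "Detected in all", "Detected in some",
    "Detected in many", "Detected in all", NA
  ))
  best <- c(N1 = "A", N2 = "A", N3 = "D", N4 = "B", N5 = "B", N6 = "F")
  # truth table: keep (A, some), drop (A, all), drop (D, some),
  # keep (B, many), drop (B, all), drop (F, NA)
  expect_identical(filter_interactors(nb, best, u), c("N1", "N4"))
  # a neighbor absent from both datasets (class F) is removed
  expect_identical(filter_interactors("N6", best, u), character(0))
})

test_that("compartment pruning drops disallowed localization pairs", {
  ids <- c("a", "b", "c", "d", "e", "f")
  u <- toy_universe(ids, loc_set3 = c(
    "Extracellular", "Cytosol", "Extracellular", "Extracellular",
    "Plasma membrane", NA
  ))
  edges <- ppi_edge_table(data.frame(
    protein_a = c("a", "c", "a", "b", "b"),
    protein_b = c("b", "d", "e", "e", "f"),
    confidence = 0.9, channels = "experiments"
  ))
  kept <- compartment_prune(edges, u)
  # extracellular-cytosol (a-b) removed; same-compartment (c-d),
  # membrane-extracellular (a-e), membrane-cytosol (b-e) and NA (b-f) kept
  expect_equal(nrow(kept), 3L + 1L)
  expect_false(any(kept$protein_a == "a" & kept$protein_b == "b"))
  # NA treated as incompatible when asked
  strict <- compartment_prune(edges, u, na_compatible = FALSE)
  expect_false(any(strict$protein_b == "f"))
})

test_that("tissue confinement drops interactors expressed only in the other dataset", {
  ids <- c("N1", "N2", "N3")
  u <- toy_universe(ids)
  ch <- assign_expression_groups(
    toy_matrix(c(100, 0, 50), ids, "Fibroblasts", dataset = "choroid_rpe"),
    u, grouping_policy(universe_size = 3, top_frac = 0.5))
  tabs <- list(choroid_rpe = ch)
  # N1 and N3 are A/B in choroid; N2 is not (zero there)
  kept <- apply_tissue_confinement(ids, "choroid_rpe", tabs)
  expect_identical(kept, c("N1", "N3"))
  expect_error(apply_tissue_confinement(ids, "nope", tabs), "nope")
})

test_that("layer assignment: overrides beat rules, first rule wins, else default", {
  nodes <- data.frame(
    gene_id = c("CD53", "n2", "n3", "n4"),
    sysgo_set3 = c("Metabolism", "Immune system and Inflammation",
      "Immune system and Inflammation", "Other"),
    loc_set3 = c("Cytosol", "Extracellular", "Cytosol", NA),
    stringsAsFactors = FALSE
  )
  rules <- layer_rules(
    rules = list(
      list(field = "sysgo_set3", values = "Immune system and Inflammation", layer = "AL1"),
      list(field = "loc_set3", values = "Extracellular", layer = "AL2")
    ),
    overrides = c(CD53 = "AL1")
  )
  got <- assign_layers(nodes, rules)
  # CD53 forced to AL1 by override although no rule matches it;
  # n2 matches both rules, the first wins; n4 matches none -> unassigned
  expect_identical(unname(got), c("AL1", "AL1", "AL1", "unassigned"))
  expect_warning(
    assign_layers(nodes[1:2, ], layer_rules(overrides = c(GHOST = "AL3"))),
    "absent"
  )
})

test_that("the shipped override file pins the 22 anchor proteins to their layers", {
  rules <- read_layer_rules(
    system.file("extdata", "seed_layer_overrides.yaml", package = "rccnet")
  )
  expect_length(rules$overrides, 22L)
  nodes <- data.frame(gene_id = names(rules$overrides), stringsAsFactors = FALSE)
  got <- assign_layers(nodes, rules)
  expect_identical(unname(got["CD53"]), "AL1")
  expect_identical(unname(got["COL8A1"]), "AL2")
  expect_identical(unname(got["SLC16A8"]), "AL5")
  expect_true(all(got %in% ANATOMICAL_LAYERS))
})

test_that("node filters are monotone and order-invariant", {
  nb <- paste0("N", 1:6)
  u <- toy_universe(nb,
    loc_set3 = c("Extracellular", "Cytosol", "Extracellular", "Cytosol",
      "Plasma membrane", "Extracellular"),
    tissue = rep("Detected in some", 6))
  best <- setNames(c("A", "B", "A", "D", "B", "A"), nb)
  edges <- ppi_edge_table(data.frame(
    protein_a = "SEED", protein_b = nb,
    confidence = 0.9, channels = "experiments"
  ))
  useed <- toy_universe(c("SEED", nb),
    loc_set3 = c("Cytosol", "Extracellular", "Cytosol", "Extracellular",
      "Cytosol", "Plasma membrane", "Extracellular"),
    tissue = rep("Detected in some", 7))
  filt_then_prune <- {
    kept <- filter_interactors(nb, best, useed)
    e <- edges[edges$protein_b %in% kept, , drop = FALSE]
    pruned <- compartment_prune(e, useed)
    sort(pruned$protein_b)
  }
  prune_then_filt <- {
    pruned <- compartment_prune(edges, useed)
    kept <- filter_interactors(pruned$protein_b, best, useed)
    sort(kept)
  }
  expect_identical(filt_then_prune, prune_then_filt)
  # monotone: each stage's node set is a subset of the previous
  kept1 <- filter_interactors(nb, best, useed)
  expect_true(all(kept1 %in% nb))
  pruned <- compartment_prune(edges[edges$protein_b %in% kept1, ], useed)
  expect_true(all(pruned$protein_b %in% kept1))
})

test_that("subnetwork export round-trips and SIF has one line per edge", {
  ids <- c("S1", "N1", "N2", "N3")
  u <- toy_universe(ids,
    sysgo_set3 = c("Metabolism", "ECM organization", "Other", "Other"),
    loc_set3 = rep("Cytosol", 4), tissue = rep("Detected in some", 4))
  best <- setNames(c("A", "A", "B", "A"), ids)
  ppi <- ppi_edge_table(data.frame(
    protein_a = "S1", protein_b = c("N1", "N2", "N3"),
    confidence = c(0.8, 0.7, 0.6), channels = "experiments"
  ))
  g <- build_subnetwork("S1", ppi, best, u)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  td <- withr::local_tempdir()
  gml <- file.path(td, "net.graphml")
  export_network(g, gml, "graphml")
  g2 <- import_network(gml)
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_identical(
    sort(paste(igraph::V(g2)$name, igraph::V(g2)$layer)),
    sort(paste(igraph::V(g)$name, igraph::V(g)$layer))
  )
  sif <- file.path(td, "net.sif")
  export_network(g, sif, "sif")
  expect_length(readLines(sif), 3L)
  # an empty graph still exports valid documents
  g0 <- build_subnetwork(character(0), ppi, best, u)
  export_network(g0, gml, "graphml")
  expect_equal(igraph::vcount(import_network(gml)), 0L)
  expect_error(export_network(g, file.path(td, "x"), "dot"), "arg")
})

test_that("every interactor in a built subnetwork is adjacent to a seed", {
  gen <- generate_bundle(small_config(), withr::local_tempdir())
  b <- load_bundle(gen$paths$bundle)
  tabs <- lapply(b$matrices, assign_expression_groups, universe = b$universe,
    policy = grouping_policy(universe_size = nrow(b$universe)))
  best <- best_group(tabs)
  seeds <- gen$manifest$planted$seeds
  g <- build_subnetwork(seeds, b$ppi, best, b$universe, group_tables = tabs)
  inter <- igraph::V(g)$name[igraph::V(g)$role == "interactor"]
  for (v in inter) {
    nbrs <- igraph::neighbors(g, v)$name
    expect_true(any(nbrs %in% seeds))
  }
  # every surviving edge satisfies the confidence threshold
  expect_true(all(igraph::E(g)$confidence >= 0.5))
})
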