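#' Configuration for the synthetic input-bundle generator
#'
#' The generator emulates the study's input bundle at its published scale:
#' a 19,300-gene protein-coding universe; a choroid/RPE dataset with 10
#' cell types (delivered as 11 columns, two pre-merge Schwann-cell
#' clusters); a 7-cell-type neural-retina dataset; 412 disease
#' associations scored in `[0, 1]`; 11 phenocopy-exclusion sets; 10 other
#' age-related-disease sets; and a first-shell-style PPI table with
#' confidence scores and evidence channels.  Expression is zero-inflated
#' log-normal; per-dataset absence fractions match the published unmapped
#' fractions (3322/19,300 and 5838/19,300).  Ground truth is planted for
#' every downstream contract: a forced top-quota class-A set in one cell
#' type, 22 seed genes constructed to be specificity group 1a with best
#' group A, qualifying and decoy PPI partners per seed, and one
#' enrichment-planted functional class among the risk genes.
#'
#' @param seed Integer root seed; every table draws from a deterministic
#'   child stream, so adding a table never perturbs earlier tables.
#' @param n_genes Universe size.
#' @param n_risk Number of risk-gene associations.
#' @param n_unmapped_risk Association rows under names absent from the
#'   universe (exercise the unmapped report).
#' @param zero_frac Zero-inflation fraction among present genes.
#' @param meanlog,sdlog Log-normal expression parameters.
#' @param absent_frac Named fractions of universe genes absent per dataset.
#' @param alias_frac Fraction of genes carrying aliases.
#' @param assoc_alias_frac Fraction of association rows written under an
#'   alias instead of the primary symbol.
#' @param score_shape1,score_shape2 Beta parameters of the association
#'   scores.
#' @param n_exclusion_sets,exclusion_set_size,exclusion_risk_overlap
#'   Phenocopy-exclusion collection: number of sets, background members
#'   per set, and how many (non-seed) risk genes are planted into them.
#' @param age_overlap Probability that a (non-seed) risk gene belongs to
#'   at least one other age-related disease set.
#' @param age_set_size Background members per age-disease set.
#' @param tissue_marginals Probabilities of the five tissue-distribution
#'   classes plus `NA`, in the order of [TISSUE_CLASSES] then `NA`.
#' @param loc_na_frac Fraction of genes with unknown localization.
#' @param planted_enrichment `list(level, odds)`; the planted class is the
#'   first label at that level and the target set is the risk genes.
#' @param n_seeds Planted network seed genes (subset of risk genes).
#' @param interactors_per_seed Qualifying planted partners per seed.
#' @param decoys_per_seed Named counts of planted failing partners per
#'   seed: `lowconf` (confidence below 0.5), `channel` (only the `other`
#'   evidence channel) and `generic` (ubiquitously expressed partner).
#' @param background_nodes,background_edges Random PPI background.
#' @param top_cell,interactor_cell Choroid/RPE cell types receiving the
#'   forced-top class-A plant and the forced-high interactor plant.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 19300L,
                             n_risk = 412L,
                             n_unmapped_risk = 5L,
                             zero_frac = 0.10,
                             meanlog = 1, sdlog = 1.5,
                             absent_frac = c(choroid_rpe = 3322 / 19300, nr = 5838 / 19300),
                             alias_frac = 0.15,
                             assoc_alias_frac = 0.10,
                             score_shape1 = 1.2, score_shape2 = 6,
                             n_exclusion_sets = 11L,
                             exclusion_set_size = 30L,
                             exclusion_risk_overlap = 20L,
                             age_overlap = 0.70,
                             age_set_size = 400L,
                             tissue_marginals = c(9349, 5335, 3176, 668, 198, 574) / 19300,
                             loc_na_frac = 313 / 19300,
                             planted_enrichment = list(level = "sysgo_set2", odds = 4),
                             n_seeds = 22L,
                             interactors_per_seed = 8L,
                             decoys_per_seed = c(lowconf = 4L, channel = 3L, generic = 3L),
                             background_nodes = 500L,
                             background_edges = 1000L,
                             top_cell = "Fibroblasts",
                             interactor_cell = "RPE cells") {
  probs <- c(
    zero_frac, absent_frac, alias_frac, assoc_alias_frac, age_overlap,
    tissue_marginals, loc_na_frac
  )
  if (any(probs < 0 | probs > 1)) stopf("synthetic config: probabilities must lie in [0, 1]")
  if (abs(sum(tissue_marginals) - 1) > 1e-9) stopf("synthetic config: tissue_marginals must sum to 1")
  n_int <- n_seeds * interactors_per_seed
  if (n_risk + n_int + background_nodes > n_genes) {
    stopf("synthetic config: planted sets larger than the universe")
  }
  quota <- round_half_up(0.01 * n_genes)
  if (n_seeds > quota) stopf("synthetic config: n_seeds exceeds the class-A quota (%d)", quota)
  structure(as.list(environment()), class = "SyntheticConfig")
}

# Label tables: 321 set-1 classes -> 58 set-2 groups -> the 15 broad
# set-3 classes; 47 loc-1 -> 39 loc-2 -> 8 loc-3 compartments.
sysgo_label_tables <- function() {
  set3 <- c(
    "Signaling", "Metabolism",
    "Protein translation, folding, modification and degradation",
    "Transcription", "Unknown", "Cytoskeleton", "Organelles", "Other",
    "Immune system and Inflammation",
    "Chromatin organization and DNA repair",
    "Neuronal System, synapses, channels", "ECM organization",
    "Cell junction and adhesion", "Developmental", "DNA Replication"
  )
  set2 <- sprintf("%s / G%02d", set3[((seq_len(58) - 1L) %% 15L) + 1L], seq_len(58))
  set2_to_set3 <- stats::setNames(set3[((seq_len(58) - 1L) %% 15L) + 1L], set2)
  set1 <- sprintf("C%03d", seq_len(321))
  set1_to_set2 <- stats::setNames(set2[((seq_len(321) - 1L) %% 58L) + 1L], set1)
  loc3 <- loc_set3_levels()
  loc2 <- sprintf("%s / L%02d", loc3[((seq_len(39) - 1L) %% 8L) + 1L], seq_len(39))
  loc2_to_loc3 <- stats::setNames(loc3[((seq_len(39) - 1L) %% 8L) + 1L], loc2)
  loc1 <- sprintf("%s / l%02d", loc2[((seq_len(47) - 1L) %% 39L) + 1L], seq_len(47))
  loc1_to_loc2 <- stats::setNames(loc2[((seq_len(47) - 1L) %% 39L) + 1L], loc1)
  list(
    set1 = set1, set2 = set2, set3 = set3,
    set1_to_set2 = set1_to_set2, set2_to_set3 = set2_to_set3,
    loc1 = loc1, loc2 = loc2, loc3 = loc3,
    loc1_to_loc2 = loc1_to_loc2, loc2_to_loc3 = loc2_to_loc3
  )
}

choroid_cell_types <- function() {
  c(
    "Schwann cells 1", "Schwann cells 2", "Melanocytes",
    "Endothelial cells", "Smooth muscle cells", "Fibroblasts",
    "RPE cells", "B cells", "T/NK cells", "Monocytes/macrophages",
    "Mast cells"
  )
}

nr_cell_types <- function() {
  c(
    "Rod photoreceptors", "Cone photoreceptors", "Retinal ganglion cells",
    "Horizontal cells", "Bipolar cells", "Amacrine cells", "Muller glia"
  )
}

#' Plant a class enrichment into a gene universe
#'
#' Raises the membership probability of one annotation class among a
#' target gene set so that the expected sample odds ratio against the
#' rest of the universe equals `odds`: with background membership rate
#' `p0`, target genes are reassigned to the class with probability
#' `p1 = odds * p0 / (1 - p0 + odds * p0)` (so the expected odds
#' `p1/(1-p1)` over `p0/(1-p0)` is exactly `odds`).  Reassignment keeps
#' the annotation hierarchy consistent: a gene moved into a `sysgo_set2`
#' class receives a `sysgo_set1` class belonging to it, and `sysgo_set3`
#' follows the set-2 mapping; a target gene drawn out of the class is
#' moved to a random other class.
#'
#' @param universe A `GeneUniverse`.
#' @param class_label Class to enrich; must already exist in the universe
#'   at that level.
#' @param target_set Character vector of target gene ids.
#' @param odds Target expected odds ratio, `>= 1`.
#' @param level Annotation level (currently `sysgo_set2`).
#' @param seed Integer seed for the reassignment draws.
#' @return List with `universe` (modified), `p0`, `p1`, `expected_k`
#'   (expected class count in the target set) and `k` (the realized
#'   count).
#' @export
plant_enrichment <- function(universe, class_label, target_set, odds,
                             level = "sysgo_set2", seed = 1L) {
  stopifnot(inherits(universe, "GeneUniverse"))
  if (level != "sysgo_set2") stopf("plant_enrichment: only sysgo_set2 is supported")
  if (odds < 1) stopf("plant_enrichment: odds must be >= 1")
  target_set <- unique(target_set)
  if (!all(target_set %in% universe$gene_id)) {
    stopf("plant_enrichment: target set not contained in the universe")
  }
  in_t <- universe$gene_id %in% target_set
  if (!any(universe[[level]][!in_t] == class_label, na.rm = TRUE)) {
    stopf("plant_enrichment: class '%s' absent from the background", class_label)
  }
  p0 <- mean(universe[[level]][!in_t] == class_label, na.rm = TRUE)
  p1 <- odds * p0 / (1 - p0 + odds * p0)
  if (p1 > 1) stopf("plant_enrichment: infeasible odds (membership probability > 1)")

  # consistent label triples observed in the universe
  trip <- unique(universe[!is.na(universe$sysgo_set2),
    c("sysgo_set1", "sysgo_set2", "sysgo_set3")])
  in_class <- trip[trip$sysgo_set2 == class_label, , drop = FALSE]
  out_class <- trip[trip$sysgo_set2 != class_label, , drop = FALSE]
  if (!nrow(in_class) || !nrow(out_class)) {
    stopf("plant_enrichment: need both in-class and out-of-class annotation triples")
  }

  u <- as.data.frame(universe)
  idx <- which(in_t)
  set.seed(seed)
  member <- stats::runif(length(idx)) < p1
  pick_in <- sample.int(nrow(in_class), sum(member), replace = TRUE)
  u[idx[member], c("sysgo_set1", "sysgo_set2", "sysgo_set3")] <-
    in_class[pick_in, , drop = FALSE]
  move_out <- !member & !is.na(u$sysgo_set2[idx]) & u$sysgo_set2[idx] == class_label
  if (any(move_out)) {
    pick_out <- sample.int(nrow(out_class), sum(move_out), replace = TRUE)
    u[idx[move_out], c("sysgo_set1", "sysgo_set2", "sysgo_set3")] <-
      out_class[pick_out, , drop = FALSE]
  }
  u2 <- gene_universe(u)
  list(
    universe = u2, p0 = p0, p1 = p1,
    expected_k = length(idx) * p1,
    k = sum(u2[[level]][u2$gene_id %in% target_set] == class_label, na.rm = TRUE)
  )
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Writes, into `dir`: `universe.tsv`, `expr_choroid_rpe.tsv` (11 columns,
#' two pre-merge Schwann clusters), `expr_nr.tsv`, `associations.tsv`,
#' `exclusions.gmt`, `age_diseases.gmt`, `ppi.tsv`, a `bundle.yaml`
#' config consumable by [load_bundle()], and `manifest.yaml` recording
#' the planted ground truth.  Fully deterministic given `config$seed`
#' (same seed, byte-identical files).
#'
#' @param config A `SyntheticConfig` from [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths`, `config` and `manifest`
#'   (the ground-truth manifest, also written as YAML).
#' @export
generate_bundle <- function(config = synthetic_config(), dir) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- sysgo_label_tables()
  n <- config$n_genes
  genes <- sprintf("GENE%05d", seq_len(n))
  quota <- round_half_up(0.01 * n)

  ## ---- universe ----
  u <- with_stream_seed(config$seed, "universe", {
    set1 <- sample(labs$set1, n, replace = TRUE)
    loc1 <- sample(labs$loc1, n, replace = TRUE)
    loc1[stats::runif(n) < config$loc_na_frac] <- NA
    td <- sample(c(TISSUE_CLASSES, NA), n, replace = TRUE, prob = config$tissue_marginals)
    has_alias <- stats::runif(n) < config$alias_frac
    aliases <- ifelse(has_alias, paste0(genes, "-AL1"), "")
    two <- has_alias & stats::runif(n) < 0.3
    aliases[two] <- paste0(aliases[two], "|", genes[two], "-AL2")
    loc2 <- unname(labs$loc1_to_loc2[loc1])
    data.frame(
      gene_id = genes, aliases = aliases,
      sysgo_set1 = set1,
      sysgo_set2 = unname(labs$set1_to_set2[set1]),
      sysgo_set3 = unname(labs$set2_to_set3[labs$set1_to_set2[set1]]),
      loc_set1 = loc1, loc_set2 = loc2,
      loc_set3 = unname(labs$loc2_to_loc3[loc2]),
      tissue_distribution = td,
      stringsAsFactors = FALSE
    )
  })

  ## ---- planted genes ----
  planted <- with_stream_seed(config$seed, "planted", {
    risk <- sort(sample(genes, config$n_risk))
    seeds <- sort(sample(risk, config$n_seeds))
    pool <- setdiff(genes, risk)
    n_int <- config$n_seeds * config$interactors_per_seed
    interactors <- sort(sample(pool, n_int))
    # remaining forced-top genes fill the class-A quota in the top cell
    extra_a <- sample(setdiff(genes, c(seeds, interactors)), quota - config$n_seeds)
    planted_a <- sort(c(seeds, extra_a))
    list(risk = risk, seeds = seeds, interactors = interactors, planted_a = planted_a)
  })

  # seeds must be tissue-restricted and disease-private (group 1a);
  # planted interactors must not be ubiquitous (the interactor filter)
  u$tissue_distribution[u$gene_id %in% planted$seeds] <- "Detected in some"
  u$tissue_distribution[u$gene_id %in% planted$interactors] <-
    with_stream_seed(config$seed, "interactor_tissue",
      sample(c("Detected in some", "Detected in many", "Detected in single"),
        length(planted$interactors), replace = TRUE))

  ## ---- planted enrichment ----
  planted_class <- labs$set2[1]
  pe <- plant_enrichment(gene_universe(u), planted_class, planted$risk,
    odds = config$planted_enrichment$odds,
    seed = child_seed(config$seed, "enrichment"))
  universe <- pe$universe

  ## ---- expression matrices ----
  make_matrix <- function(ds, cell_types, plant_top = NULL) {
    with_stream_seed(config$seed, paste0("expr_", ds), {
      protected <- unique(c(
        if (!is.null(plant_top)) unlist(plant_top$genes),
        if (ds == "choroid_rpe") planted$seeds
      ))
      n_abs <- round(config$absent_frac[[ds]] * n)
      absent <- sample(setdiff(genes, protected), n_abs)
      present <- setdiff(genes, absent)
      m <- matrix(
        stats::rlnorm(length(present) * length(cell_types),
          meanlog = config$meanlog, sdlog = config$sdlog),
        nrow = length(present), ncol = length(cell_types),
        dimnames = list(present, cell_types)
      )
      zero <- matrix(stats::runif(length(m)) < config$zero_frac, nrow = nrow(m))
      m[zero] <- 0
      if (!is.null(plant_top)) {
        for (p in plant_top$plants) {
          tgt <- p$genes
          col <- p$cell_type
          m[tgt, col] <- max(m[, col]) + rev(seq_along(tgt))
        }
      }
      m
    })
  }
  expr_ch <- make_matrix("choroid_rpe", choroid_cell_types(),
    plant_top = list(
      genes = c(planted$planted_a, planted$interactors),
      plants = list(
        list(cell_type = config$top_cell, genes = planted$planted_a),
        list(cell_type = config$interactor_cell, genes = planted$interactors)
      )
    ))
  expr_nr <- make_matrix("nr", nr_cell_types())

  ## ---- associations ----
  assoc <- with_stream_seed(config$seed, "associations", {
    score <- stats::rbeta(config$n_risk, config$score_shape1, config$score_shape2)
    score[planted$risk %in% planted$seeds] <- stats::runif(config$n_seeds, 0.6, 0.95)
    raw <- planted$risk
    alias_map <- attr(universe, "alias_map")
    has_alias <- raw %in% unname(alias_map)
    use_alias <- has_alias & stats::runif(length(raw)) < config$assoc_alias_frac
    first_alias <- vapply(raw[use_alias], function(g) {
      names(alias_map)[match(g, unname(alias_map))]
    }, character(1))
    raw[use_alias] <- first_alias
    df <- data.frame(gene = raw, disease_id = "AMD", score = round(score, 6),
      stringsAsFactors = FALSE)
    # one gene under both primary and alias (max-score reconciliation)
    dup_cand <- which(use_alias)
    if (length(dup_cand)) {
      g <- planted$risk[dup_cand[1]]
      df <- rbind(df, data.frame(gene = g, disease_id = "AMD",
        score = round(max(0, df$score[dup_cand[1]] - 0.05), 6)))
    }
    if (config$n_unmapped_risk > 0) {
      df <- rbind(df, data.frame(
        gene = sprintf("UNKNOWN%03d", seq_len(config$n_unmapped_risk)),
        disease_id = "AMD",
        score = round(stats::rbeta(config$n_unmapped_risk,
          config$score_shape1, config$score_shape2), 6)
      ))
    }
    df[order(df$gene), , drop = FALSE]
  })

  ## ---- exclusion gene sets (phenocopy degenerations) ----
  phenocopy_names <- c(
    "Retinitis pigmentosa", "Stargardt disease",
    "Congenital stationary night blindness", "Cone rod dystrophy",
    "Leber congenital amaurosis", "Infantile Refsum disease",
    "Usher syndrome", "Bardet-Biedl syndrome", "Joubert syndrome",
    "Alport syndrome", "Cockayne syndrome"
  )[seq_len(min(11L, config$n_exclusion_sets))]
  exclusions <- with_stream_seed(config$seed, "exclusions", {
    non_risk <- setdiff(genes, planted$risk)
    overlap <- sample(setdiff(planted$risk, planted$seeds),
      config$exclusion_risk_overlap)
    sets <- lapply(seq_along(phenocopy_names), function(i) {
      sort(sample(non_risk, config$exclusion_set_size))
    })
    slot <- rep(seq_along(sets), length.out = length(overlap))
    for (i in seq_along(overlap)) {
      sets[[slot[i]]] <- sort(c(sets[[slot[i]]], overlap[i]))
    }
    stats::setNames(sets, phenocopy_names)
  })

  ## ---- age-related disease sets ----
  age_names <- c(
    "Coronary heart disease", "Diabetes mellitus", "Rheumatoid arthritis",
    "Alzheimer's disease", "Obesity", "Multiple sclerosis", "Asthma",
    "Systemic scleroderma", "Osteoporosis", "Parkinson's disease"
  )
  age_sets <- with_stream_seed(config$seed, "age_sets", {
    sets <- lapply(age_names, function(nm) {
      sample(setdiff(genes, planted$seeds), config$age_set_size)
    })
    names(sets) <- age_names
    non_seed_risk <- setdiff(planted$risk, planted$seeds)
    in_any <- stats::runif(length(non_seed_risk)) < config$age_overlap
    for (g in non_seed_risk[in_any]) {
      k <- 1L + stats::rpois(1, 1)
      for (s in sample(seq_along(sets), min(k, length(sets)))) {
        sets[[s]] <- c(sets[[s]], g)
      }
    }
    # risk genes NOT drawn for membership must stay out of every set
    for (i in seq_along(sets)) {
      sets[[i]] <- sort(unique(setdiff(
        sets[[i]],
        c(planted$seeds, non_seed_risk[!in_any])
      )))
    }
    sets
  })

  ## ---- PPI table ----
  ppi <- with_stream_seed(config$seed, "ppi", {
    rows <- list()
    add <- function(a, b, conf, ch) {
      rows[[length(rows) + 1L]] <<- data.frame(
        protein_a = a, protein_b = b, confidence = round(conf, 3),
        channels = ch, stringsAsFactors = FALSE
      )
    }
    ipps <- config$interactors_per_seed
    generic_pool <- genes[universe$tissue_distribution %in% "Detected in all"]
    other_pool <- setdiff(genes, c(planted$seeds, planted$interactors))
    for (i in seq_along(planted$seeds)) {
      s <- planted$seeds[i]
      mine <- planted$interactors[((i - 1L) * ipps + 1L):(i * ipps)]
      add(s, mine, stats::runif(ipps, 0.5, 0.99),
        sample(c("experiments", "databases", "experiments,databases"),
          ipps, replace = TRUE))
      d <- config$decoys_per_seed
      if (d[["lowconf"]] > 0) {
        add(s, sample(other_pool, d[["lowconf"]]),
          stats::runif(d[["lowconf"]], 0.05, 0.49), "experiments")
      }
      if (d[["channel"]] > 0) {
        add(s, sample(other_pool, d[["channel"]]),
          stats::runif(d[["channel"]], 0.5, 0.95), "other")
      }
      if (d[["generic"]] > 0) {
        add(s, sample(generic_pool, d[["generic"]]),
          stats::runif(d[["generic"]], 0.5, 0.95), "experiments")
      }
    }
    bg_nodes <- sample(genes, config$background_nodes)
    a <- sample(bg_nodes, config$background_edges, replace = TRUE)
    b <- sample(bg_nodes, config$background_edges, replace = TRUE)
    keep <- a != b
    add(a[keep], b[keep], stats::runif(sum(keep), 0.1, 0.95),
      sample(c("experiments", "databases", "other", "experiments,other"),
        sum(keep), replace = TRUE))
    ppi_edge_table(do.call(rbind, rows))
  })

  ## ---- expected ground truth ----
  tiers <- tier_of(universe$tissue_distribution[match(planted$risk, universe$gene_id)])
  in_age <- vapply(planted$risk, function(g) {
    any(vapply(age_sets, function(s) g %in% s, logical(1)))
  }, logical(1))
  expected_group <- ifelse(tiers == "generic", "3",
    ifelse(tiers == "intermediate", "2", ifelse(in_age, "1b", "1a")))

  ## ---- write files ----
  paths <- list(
    universe = file.path(dir, "universe.tsv"),
    expr_choroid_rpe = file.path(dir, "expr_choroid_rpe.tsv"),
    expr_nr = file.path(dir, "expr_nr.tsv"),
    associations = file.path(dir, "associations.tsv"),
    exclusions = file.path(dir, "exclusions.gmt"),
    age_sets = file.path(dir, "age_diseases.gmt"),
    ppi = file.path(dir, "ppi.tsv"),
    bundle = file.path(dir, "bundle.yaml"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_gene_universe(universe, paths$universe)
  write_matrix_tsv(expr_ch, paths$expr_choroid_rpe)
  write_matrix_tsv(expr_nr, paths$expr_nr)
  write_tsv(assoc, paths$associations)
  write_gmt(exclusions, paths$exclusions)
  write_gmt(age_sets, paths$age_sets)
  write_ppi_table(ppi, paths$ppi)

  bundle_cfg <- list(
    paths = list(
      universe = "universe.tsv",
      expression = list(choroid_rpe = "expr_choroid_rpe.tsv", nr = "expr_nr.tsv"),
      associations = "associations.tsv",
      exclusions = "exclusions.gmt",
      age_sets = "age_diseases.gmt",
      ppi = "ppi.tsv"
    ),
    policies = list(
      merge = list(choroid_rpe = list(
        `Schwann cells 1` = "Schwann cells",
        `Schwann cells 2` = "Schwann cells"
      )),
      top_frac = 0.01, drop_frac = 0.05, z_threshold = 2, min_conf = 0.5
    )
  )
  yaml::write_yaml(bundle_cfg, paths$bundle)

  manifest <- list(
    seed = config$seed,
    n_genes = n,
    quota = quota,
    planted = list(
      risk_genes = planted$risk,
      seeds = planted$seeds,
      interactors_by_seed = stats::setNames(
        lapply(seq_along(planted$seeds), function(i) {
          ip <- config$interactors_per_seed
          planted$interactors[((i - 1L) * ip + 1L):(i * ip)]
        }),
        planted$seeds
      ),
      class_a = list(
        dataset = "choroid_rpe", cell_type = config$top_cell,
        genes = planted$planted_a
      ),
      enrichment = list(
        level = "sysgo_set2", class = planted_class,
        odds = config$planted_enrichment$odds,
        p0 = pe$p0, p1 = pe$p1, expected_k = pe$expected_k, k = pe$k
      ),
      specificity_groups = as.list(stats::setNames(expected_group, planted$risk))
    ),
    row_counts = list(
      universe = nrow(universe),
      expr_choroid_rpe = nrow(expr_ch),
      expr_nr = nrow(expr_nr),
      associations = nrow(assoc),
      exclusion_sets = length(exclusions),
      age_sets = length(age_sets),
      ppi_edges = nrow(ppi)
    )
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(list(dir = dir, paths = paths, config = config, manifest = manifest))
}
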