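#' Run the analysis pipeline
#'
#' Subcommand-driven orchestration over a run config.  Stages:
#' \describe{
#'   \item{`simulate`}{generate a synthetic input bundle into
#'     `<outdir>/bundle` and point the run at it.}
#'   \item{`classify`}{load the bundle, merge clusters, assign expression
#'     groups per dataset, compute best groups, z-scores and z-flags.}
#'   \item{`prioritize`}{prune the association list, filter to the
#'     high-confidence set, assign specificity groups and overlap counts.}
#'   \item{`enrich`}{functional-class enrichment of the high-confidence
#'     set and localization distributions per specificity group.}
#'   \item{`network`}{select seeds, build the filtered, compartment-pruned,
#'     layered subnetwork, export GraphML/SIF/TSV.}
#'   \item{`all`}{chain every stage in order.}
#' }
#' Each stage reads its upstream artifacts from `outdir` and fails with
#' an error naming the missing artifact if a required stage has not run.
#' No stage mutates its inputs; rerunning with an identical config and
#' seed reproduces byte-identical outputs.  A run manifest
#' (`run_manifest.json`: parameters, seed, input checksums, row counts,
#' stage durations) is updated after every stage.
#'
#' @param stage One of `"simulate"`, `"classify"`, `"prioritize"`,
#'   `"enrich"`, `"network"`, `"all"`.
#' @param config A run config: list (or YAML path) with `outdir`, `seed`,
#'   and either `bundle` (path to a bundle YAML for [load_bundle()]) or
#'   nothing (then `simulate` must run first).  Optional `policies`
#'   overrides are passed through to the bundle.
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "classify",
                                   "prioritize", "enrich", "network"),
                         config) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% stopf("run config: 'outdir' required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stages <- if (stage == "all") {
    c("simulate"[is.null(config$bundle)], "classify", "prioritize", "enrich", "network")
  } else {
    stage
  }
  manifest_path <- file.path(outdir, "run_manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(seed = seed, stages = list())
  }

  need <- function(path, what, producer) {
    if (!file.exists(path)) {
      stopf("missing upstream artifact '%s' (%s); run stage '%s' first",
        path, what, producer)
    }
    path
  }
  bundle_path <- function() {
    config$bundle %||% file.path(outdir, "bundle", "bundle.yaml")
  }

  for (st in stages) {
    t0 <- Sys.time()
    counts <- list()
    if (st == "simulate") {
      gen <- generate_bundle(
        synthetic_config(seed = seed),
        file.path(outdir, "bundle")
      )
      counts <- gen$manifest$row_counts
    } else if (st == "classify") {
      b <- load_bundle(need(bundle_path(), "bundle config", "simulate"),
        manifest_path = file.path(outdir, "load_manifest.yaml"))
      policy <- grouping_policy(
        top_frac = b$policies$top_frac, upper_frac = b$policies$upper_frac,
        middle_frac = b$policies$middle_frac, lower_frac = b$policies$lower_frac,
        universe_size = nrow(b$universe)
      )
      tabs <- lapply(b$matrices, assign_expression_groups,
        universe = b$universe, policy = policy)
      for (ds in names(tabs)) {
        write_group_table(tabs[[ds]], file.path(outdir, paste0("groups_", ds, ".tsv")))
        z <- compute_zscores(b$matrices[[ds]])
        write_zscore_table(z, file.path(outdir, paste0("zscores_", ds, ".tsv")))
        fl <- flag_specific(z, b$policies$z_threshold)
        write_matrix_tsv(1L * fl, file.path(outdir, paste0("zflags_", ds, ".tsv")))
      }
      best <- best_group(tabs)
      write_tsv(
        data.frame(gene_id = names(best), best_group = unname(best)),
        file.path(outdir, "best_groups.tsv")
      )
      counts <- lapply(tabs, function(t) sum(t$present))
    } else if (st == "prioritize") {
      b <- load_bundle(need(bundle_path(), "bundle config", "simulate"))
      bg <- read_tsv_strict(need(file.path(outdir, "best_groups.tsv"),
        "best expression groups", "classify"))
      best <- stats::setNames(bg$best_group, bg$gene_id)
      pruned <- prune_risk_genes(b$associations, b$universe, b$exclusions,
        drop_frac = b$policies$drop_frac)
      records <- risk_gene_records(pruned, best, b$universe, b$age_sets,
        allowed = b$policies$allowed_best)
      write_tsv(as.data.frame(records), file.path(outdir, "risk_genes.tsv"))
      counts <- list(
        pruned = nrow(pruned),
        high_confidence = sum(!is.na(records$specificity_group))
      )
    } else if (st == "enrich") {
      b <- load_bundle(need(bundle_path(), "bundle config", "simulate"))
      rec <- read_tsv_strict(need(file.path(outdir, "risk_genes.tsv"),
        "risk-gene table", "prioritize"))
      hc <- rec$gene_id[!is.na(rec$specificity_group)]
      enr <- fisher_enrichment(hc, b$universe, level = "sysgo_set2")
      write_enrichment(enr, file.path(outdir, "enrichment_sysgo_set2.tsv"))
      groups <- split(
        rec$gene_id[!is.na(rec$specificity_group)],
        rec$specificity_group[!is.na(rec$specificity_group)]
      )
      write_tsv(localization_distribution(groups, b$universe, "loc_set3"),
        file.path(outdir, "localization_distribution.tsv"))
      counts <- list(enrichment_classes = nrow(enr))
    } else if (st == "network") {
      b <- load_bundle(need(bundle_path(), "bundle config", "simulate"))
      rec <- read_tsv_strict(need(file.path(outdir, "risk_genes.tsv"),
        "risk-gene table", "prioritize"))
      bg <- read_tsv_strict(need(file.path(outdir, "best_groups.tsv"),
        "best expression groups", "classify"))
      best <- stats::setNames(bg$best_group, bg$gene_id)
      rec$specificity_group <- as.character(rec$specificity_group)
      class(rec) <- c("RiskGeneTable", "data.frame")
      seeds <- select_seed_genes(rec, groups = b$policies$seed_groups,
        expr = b$policies$seed_expr)
      if (is.null(b$ppi)) stopf("missing upstream artifact: PPI table (bundle has none)")
      policy <- grouping_policy(universe_size = nrow(b$universe))
      tabs <- lapply(b$matrices, assign_expression_groups,
        universe = b$universe, policy = policy)
      zf <- lapply(b$matrices, function(m) flag_specific(compute_zscores(m),
        b$policies$z_threshold))
      g <- build_subnetwork(seeds, b$ppi, best, b$universe,
        group_tables = tabs, zflags = zf,
        min_conf = b$policies$min_conf, channels = b$policies$channels,
        compat = b$compat, rules = b$layer_rules)
      export_network(g, file.path(outdir, "network.graphml"), "graphml")
      export_network(g, file.path(outdir, "network.sif"), "sif")
      export_network(g, file.path(outdir, "network_edges.tsv"), "tsv")
      nodes <- data.frame(
        gene_id = igraph::V(g)$name, role = igraph::V(g)$role,
        layer = igraph::V(g)$layer, best_group = igraph::V(g)$best_group,
        z_flagged = igraph::V(g)$z_flagged, stringsAsFactors = FALSE
      )
      write_tsv(nodes, file.path(outdir, "network_nodes.tsv"))
      counts <- list(
        seeds = length(seeds),
        nodes = igraph::vcount(g), edges = igraph::ecount(g)
      )
    }
    manifest$stages[[st]] <- list(
      completed = TRUE,
      duration_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      counts = counts
    )
    message(sprintf("[rccnet] stage %-10s done in %5.1fs  (%s)",
      st, manifest$stages[[st]]$duration_s,
      paste(names(counts), unlist(counts), sep = "=", collapse = ", ")))
  }
  manifest$seed <- seed
  manifest$parameters <- config$policies %||% list()
  bp <- bundle_path()
  if (file.exists(bp)) manifest$bundle_checksum <- unname(tools::md5sum(bp))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Reproduce the risk-gene workflow chain on a bundle
#'
#' Runs the documented prioritization chain on any input bundle and
#' returns its count signature: association genes -> pruned (coding,
#' exclusion-free, bottom-quantile removed) -> high-confidence (best
#' group A/B/C) -> specificity groups 1a/1b/2/3 -> network seeds (group
#' 1a, best A/B) -> filtered first-shell interactors, plus the
#' age-disease overlap fraction.  On the published frozen inputs this is
#' the 412 -> 360 -> 307 -> 40/102/63/102 -> 22 -> 342 chain; on a
#' synthetic bundle the counts follow the generator's planted truth.
#'
#' @param bundle An `rcc_bundle` from [load_bundle()], or a path to a
#'   bundle YAML.
#' @return List of counts: `n_association_genes`, `n_pruned`,
#'   `n_high_confidence`, `group_sizes` (named 1a/1b/2/3),
#'   `overlap_fraction`, `n_seeds`, `n_interactors`.
#' @export
reproduce_workflow <- function(bundle) {
  if (is.character(bundle)) bundle <- load_bundle(bundle)
  stopifnot(inherits(bundle, "rcc_bundle"))
  if (is.null(bundle$associations)) {
    stopf("workflow reproduction requires an association table in the bundle")
  }
  policy <- grouping_policy(universe_size = nrow(bundle$universe))
  tabs <- lapply(bundle$matrices, assign_expression_groups,
    universe = bundle$universe, policy = policy)
  best <- best_group(tabs)
  pruned <- prune_risk_genes(bundle$associations, bundle$universe,
    bundle$exclusions, drop_frac = bundle$policies$drop_frac)
  records <- risk_gene_records(pruned, best, bundle$universe, bundle$age_sets)
  hc <- records[!is.na(records$specificity_group), , drop = FALSE]
  group_sizes <- vapply(c("1a", "1b", "2", "3"), function(g) {
    sum(hc$specificity_group == g)
  }, integer(1))
  overlap <- disease_overlap_summary(hc$gene_id, bundle$universe, bundle$age_sets)
  seeds <- select_seed_genes(records)
  n_int <- NA_integer_
  if (!is.null(bundle$ppi)) {
    nb <- character(0)
    for (s in seeds) {
      shell <- suppressWarnings(extract_first_shell(bundle$ppi, s,
        min_conf = bundle$policies$min_conf,
        channels = bundle$policies$channels))
      nb <- union(nb, shell$neighbors)
    }
    n_int <- length(filter_interactors(nb, best, bundle$universe))
  }
  list(
    n_association_genes = attr(pruned, "n_input"),
    n_pruned = nrow(pruned),
    n_high_confidence = nrow(hc),
    group_sizes = group_sizes,
    overlap_fraction = overlap$overlap_fraction,
    n_seeds = length(seeds),
    n_interactors = n_int
  )
}
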