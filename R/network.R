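#' Select subnetwork seed genes
#'
#' Seeds are the risk genes worth anchoring a PPI subnetwork on: by
#' default the tissue-restricted, disease-private genes (specificity group
#' `1a`) that are highly expressed (best group `A` or `B`) in at least one
#' cell type.
#'
#' @param records A `RiskGeneTable` from [risk_gene_records()].
#' @param groups Admissible specificity groups (default `"1a"`).
#' @param expr Admissible best expression groups (default `A`, `B`).
#' @return Character vector of seed gene ids, sorted.
#' @export
select_seed_genes <- function(records, groups = "1a", expr = c("A", "B")) {
  keep <- !is.na(records$specificity_group) &
    records$specificity_group %in% groups &
    records$best_group %in% expr
  sort(records$gene_id[keep])
}

#' Extract the first shell of a seed protein
#'
#' Direct interaction partners of the seed with edge confidence at or
#' above `min_conf` (inclusive; 0.5 is the conventional medium-confidence
#' cut) supported by at least one allowed evidence channel.
#'
#' @param ppi A `PPIEdgeTable`.
#' @param seed Seed gene id.
#' @param min_conf Minimum interaction confidence, inclusive.
#' @param channels Allowed evidence channels (default experimental and
#'   curated-database support).
#' @return List with `neighbors` (sorted character vector) and `edges`
#'   (the qualifying rows of `ppi`).  A seed absent from the table yields
#'   an empty shell with a warning.
#' @export
extract_first_shell <- function(ppi, seed, min_conf = 0.5,
                                channels = c("experiments", "databases")) {
  stopifnot(inherits(ppi, "PPIEdgeTable"))
  touches <- ppi$protein_a == seed | ppi$protein_b == seed
  if (!any(touches)) {
    warnf("seed '%s' absent from the PPI table; empty first shell", seed)
    return(list(neighbors = character(0), edges = ppi[0, , drop = FALSE]))
  }
  ch_ok <- vapply(
    strsplit(ppi$channels[touches], ",", fixed = TRUE),
    function(x) any(x %in% channels), logical(1)
  )
  edges <- ppi[touches, , drop = FALSE][ppi$confidence[touches] >= min_conf & ch_ok, , drop = FALSE]
  neighbors <- sort(unique(ifelse(edges$protein_a == seed, edges$protein_b, edges$protein_a)))
  rownames(edges) <- NULL
  list(neighbors = neighbors, edges = edges)
}

#' Filter interactors by expression and tissue ubiquity
#'
#' Keeps only interactors that are themselves highly expressed in at least
#' one cell type (best group `A` or `B`) and not ubiquitously expressed
#' across body tissues (`tissue_distribution != "Detected in all"`).
#' A per-entity predicate: reordering with [compartment_prune()] never
#' changes the final node set.
#'
#' @param neighbors Character vector of interactor gene ids.
#' @param best Named best-group vector from [best_group()].
#' @param universe A `GeneUniverse`.
#' @param expr Admissible best groups, default `A`, `B`.
#' @return The filtered, sorted interactor vector.
#' @export
filter_interactors <- function(neighbors, best, universe, expr = c("A", "B")) {
  stopifnot(inherits(universe, "GeneUniverse"))
  if (!length(neighbors)) return(character(0))
  bg <- unname(best[neighbors])
  bg[is.na(bg)] <- "F"
  td <- universe$tissue_distribution[match(neighbors, universe$gene_id)]
  keep <- bg %in% expr & (is.na(td) | td != "Detected in all")
  sort(neighbors[keep])
}

#' Prune edges between incompatible compartments
#'
#' Drops every edge whose endpoint `loc_set3` pair the compatibility
#' matrix disallows; endpoints with unknown localization (`NA`, or a label
#' absent from the matrix) are treated as compatible with everything
#' unless `na_compatible = FALSE`.
#'
#' @param edges A `PPIEdgeTable` (or data.frame with `protein_a`,
#'   `protein_b`).
#' @param universe A `GeneUniverse` supplying `loc_set3` per gene.
#' @param compat A `CompatibilityMatrix` (default
#'   [default_compatibility_matrix()]).
#' @param na_compatible Treat unknown localization as compatible?
#' @return The surviving edges.
#' @export
compartment_prune <- function(edges, universe,
                              compat = default_compatibility_matrix(),
                              na_compatible = TRUE) {
  stopifnot(inherits(universe, "GeneUniverse"))
  if (!nrow(edges)) return(edges)
  loc <- function(g) universe$loc_set3[match(g, universe$gene_id)]
  la <- loc(edges$protein_a)
  lb <- loc(edges$protein_b)
  known <- !is.na(la) & !is.na(lb) & la %in% rownames(compat) & lb %in% rownames(compat)
  ok <- rep(na_compatible, nrow(edges))
  ok[known] <- compat[cbind(la[known], lb[known])]
  out <- edges[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confine interactors to the seed's tissue layer
#'
#' For seeds whose biology is confined to one tissue layer (e.g. paracrine
#' factors acting within the choroid/RPE), drop interactors whose high
#' expression (`A`/`B`) occurs only in the cell types of the other
#' dataset.  An interactor highly expressed in the seed's own dataset (in
#' any cell type) is kept.
#'
#' @param neighbors Character vector of interactor gene ids.
#' @param seed_dataset Dataset id the seed is confined to (e.g.
#'   `"choroid_rpe"`).
#' @param group_tables Named list of `ExpressionGroupTable`s keyed by
#'   dataset id; must contain `seed_dataset`.
#' @param expr Expression groups that count as "expressed here".
#' @return The filtered, sorted interactor vector.
#' @export
apply_tissue_confinement <- function(neighbors, seed_dataset, group_tables,
                                     expr = c("A", "B")) {
  if (!length(neighbors)) return(character(0))
  if (!seed_dataset %in% names(group_tables)) {
    stopf("no expression-group table for dataset '%s'", seed_dataset)
  }
  tab <- group_tables[[seed_dataset]]
  g <- tab$groups[match(neighbors, rownames(tab$groups)), , drop = FALSE]
  here <- apply(g, 1, function(row) any(row %in% expr))
  here[is.na(here)] <- FALSE
  sort(neighbors[here])
}

#' Assign anatomical layers to subnetwork nodes
#'
#' Explicit overrides win; otherwise the first matching rule of the
#' ordered rule set; otherwise the default layer.  Overrides naming nodes
#' absent from the input are ignored with a warning.
#'
#' @param nodes Data.frame with columns `gene_id` and the annotation
#'   fields the rules predicate on (`sysgo_set2`, `sysgo_set3`,
#'   `loc_set3`; missing columns are treated as all-`NA`).
#' @param rules A `LayerRuleSet` (default [default_layer_rules()]).
#' @return Named character vector gene_id -> layer label.
#' @export
assign_layers <- function(nodes, rules = default_layer_rules()) {
  stopifnot(inherits(rules, "LayerRuleSet"))
  ids <- nodes$gene_id
  layer <- rep(rules$default, length(ids))
  for (r in rev(rules$rules)) {
    field <- nodes[[r$field]]
    if (is.null(field)) next
    hit <- !is.na(field) & field %in% r$values
    layer[hit] <- r$layer
  }
  # rev() above makes earlier rules overwrite later ones: first match wins
  if (length(rules$overrides)) {
    ov_genes <- names(rules$overrides)
    absent <- setdiff(ov_genes, ids)
    if (length(absent)) {
      warnf("layer override(s) for absent node(s) ignored: %s",
        paste(utils::head(absent, 5), collapse = ", "))
    }
    hit <- ov_genes %in% ids
    layer[match(ov_genes[hit], ids)] <- unname(rules$overrides[hit])
  }
  stats::setNames(layer, ids)
}

#' Build a seed-centric anatomy-layered subnetwork
#'
#' Runs the full extraction pipeline for a set of seeds: first shell per
#' seed (confidence and evidence-channel filter), interactor filter
#' (high expression, non-ubiquitous), optional tissue confinement,
#' compartment pruning of edges, and layer assignment.  Interactor sets of
#' different seeds are merged as a deduplicated union.  Each filter stage
#' only removes entities, so node sets are monotonically shrinking.
#'
#' @param seeds Character vector of seed gene ids.
#' @param ppi A `PPIEdgeTable`.
#' @param best Named best-group vector from [best_group()].
#' @param universe A `GeneUniverse`.
#' @param group_tables Named list of `ExpressionGroupTable`s by dataset.
#' @param zflags Optional named list of logical z-flag matrices by dataset
#'   (from [flag_specific()]); stored as node attributes.
#' @param min_conf,channels First-shell parameters, see
#'   [extract_first_shell()].
#' @param compat A `CompatibilityMatrix`.
#' @param rules A `LayerRuleSet`.
#' @param confine Optional named character vector seed -> dataset id; for
#'   listed seeds, interactors are confined to that dataset's cell types.
#' @return An [igraph::igraph] with node attributes `role`
#'   (`seed`/`interactor`), `sysgo_set2`, `sysgo_set3`, `loc_set3`,
#'   `layer`, `best_group`, `z_flagged`, and edge attributes `confidence`,
#'   `channels`.
#' @export
build_subnetwork <- function(seeds, ppi, best, universe, group_tables = list(),
                             zflags = list(), min_conf = 0.5,
                             channels = c("experiments", "databases"),
                             compat = default_compatibility_matrix(),
                             rules = default_layer_rules(),
                             confine = character(0)) {
  stopifnot(inherits(universe, "GeneUniverse"))
  all_edges <- list()
  kept_neighbors <- character(0)
  for (seed in seeds) {
    shell <- suppressWarnings(extract_first_shell(ppi, seed, min_conf, channels))
    nb <- filter_interactors(shell$neighbors, best, universe)
    if (seed %in% names(confine)) {
      nb <- apply_tissue_confinement(nb, confine[[seed]], group_tables)
    }
    keep <- (shell$edges$protein_a %in% c(seed, nb)) &
      (shell$edges$protein_b %in% c(seed, nb))
    all_edges[[seed]] <- shell$edges[keep, , drop = FALSE]
    kept_neighbors <- union(kept_neighbors, nb)
  }
  edges <- do.call(rbind, c(all_edges, list(ppi[0, , drop = FALSE])))
  if (!is.null(edges) && nrow(edges)) {
    edges <- ppi_edge_table(edges)
    edges <- compartment_prune(edges, universe, compat)
  } else {
    edges <- ppi[0, , drop = FALSE]
  }
  # every interactor must stay adjacent to >= 1 seed after pruning
  adj <- unique(c(
    edges$protein_b[edges$protein_a %in% seeds],
    edges$protein_a[edges$protein_b %in% seeds]
  ))
  nodes <- sort(union(seeds, intersect(kept_neighbors, adj)))
  edges <- edges[edges$protein_a %in% nodes & edges$protein_b %in% nodes, , drop = FALSE]

  idx <- match(nodes, universe$gene_id)
  node_df <- data.frame(
    name = nodes,
    role = ifelse(nodes %in% seeds, "seed", "interactor"),
    sysgo_set2 = universe$sysgo_set2[idx],
    sysgo_set3 = universe$sysgo_set3[idx],
    loc_set3 = universe$loc_set3[idx],
    best_group = {
      bg <- unname(best[nodes])
      ifelse(is.na(bg), "F", bg)
    },
    stringsAsFactors = FALSE
  )
  zf <- rep(FALSE, length(nodes))
  for (fl in zflags) {
    hit <- match(nodes, rownames(fl))
    any_fl <- apply(fl, 1, any)[hit]
    zf <- zf | ifelse(is.na(any_fl), FALSE, any_fl)
  }
  node_df$z_flagged <- zf
  node_df$layer <- unname(assign_layers(
    data.frame(gene_id = nodes,
      sysgo_set2 = node_df$sysgo_set2,
      sysgo_set3 = node_df$sysgo_set3,
      loc_set3 = node_df$loc_set3,
      stringsAsFactors = FALSE),
    rules
  ))
  edge_df <- data.frame(
    from = edges$protein_a, to = edges$protein_b,
    confidence = edges$confidence, channels = edges$channels,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edge_df, directed = FALSE, vertices = node_df)
}

#' Export a subnetwork
#'
#' GraphML carries all node and edge attributes (round-trips through
#' [import_network()]); SIF carries topology only (`node<TAB>pp<TAB>node`,
#' one line per edge, isolated nodes as a bare name); TSV is an edge list
#' with confidence and channels.
#'
#' @param graph An [igraph::igraph] from [build_subnetwork()].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"tsv"`.
#' @return The path, invisibly.
#' @export
export_network <- function(graph, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2], sep = "\t") else character(0)
    isolated <- setdiff(igraph::V(graph)$name,
      unique(c(el[, 1], el[, 2])))
    writeLines(c(lines, isolated), path)
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(
      protein_a = el[, 1], protein_b = el[, 2],
      confidence = igraph::E(graph)$confidence %||% numeric(0),
      channels = igraph::E(graph)$channels %||% character(0),
      stringsAsFactors = FALSE
    )
    write_tsv(df, path)
  }
  invisible(path)
}

#' Import a GraphML subnetwork
#' @param path GraphML file written by [export_network()].
#' @return An [igraph::igraph].
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
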