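#' Load and cross-validate a complete input bundle
#'
#' Reads every pipeline input named in a config (YAML path or list),
#' validates each table's invariants, resolves all gene names against the
#' universe, applies cluster merging, and optionally writes a load
#' manifest (row counts, unmapped counts, md5 checksums).
#'
#' Config layout (all paths relative to `base_dir`, which defaults to the
#' config file's directory):
#' \preformatted{
#' paths:
#'   universe: universe.tsv
#'   expression: {choroid_rpe: expr_choroid_rpe.tsv, nr: expr_nr.tsv}
#'   associations: associations.tsv
#'   exclusions: exclusions.gmt        # optional
#'   age_sets: age_diseases.gmt        # optional
#'   ppi: ppi.tsv                      # optional
#'   compatibility: compat.yaml        # optional, else package default
#'   layer_rules: layers.yaml          # optional, else package default
#' policies:
#'   merge: {choroid_rpe: {Schwann cells 1: Schwann cells, ...}}
#'   top_frac: 0.01
#'   drop_frac: 0.05
#'   z_threshold: 2
#'   min_conf: 0.5
#' }
#'
#' Expression-matrix rows are mapped to primary gene ids; rows that do not
#' resolve are excluded from grouping and listed in the per-dataset
#' unmapped report (they will surface as group `F` genes downstream).
#' When several raw rows resolve to the same gene (primary plus alias)
#' their values are averaged.
#'
#' @param config Path to a YAML config or an equivalent nested list.
#' @param base_dir Base directory for relative paths.
#' @param manifest_path If non-`NULL`, write the load manifest there
#'   (YAML).
#' @return A list of class `rcc_bundle` with elements `universe`,
#'   `matrices` (cluster-merged, gene-id-resolved `ExpressionMatrix`s by
#'   dataset), `associations`, `exclusions`, `age_sets`, `ppi`, `compat`,
#'   `layer_rules`, `policies`, `unmapped` (per-table unmapped name lists)
#'   and `manifest`.
#' @export
load_bundle <- function(config, base_dir = NULL, manifest_path = NULL) {
  if (is.character(config)) {
    base_dir <- base_dir %||% dirname(config)
    config <- yaml::read_yaml(config)
  }
  base_dir <- base_dir %||% "."
  paths <- config$paths %||% stopf("bundle config: missing 'paths'")
  policies <- config$policies %||% list()
  pth <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)

  universe <- read_gene_universe(pth(paths$universe %||% stopf("bundle config: paths$universe required")))
  unmapped <- list()

  matrices <- list()
  for (ds in names(paths$expression %||% list())) {
    mat <- read_expression_matrix(pth(paths$expression[[ds]]), ds)
    mm <- policies$merge[[ds]]
    if (!is.null(mm)) mat <- merge_cell_clusters(mat, unlist(mm))
    res <- resolve_gene_ids(rownames(mat$values), universe)
    unmapped[[ds]] <- res$unmapped
    mapped <- unname(res$mapping[rownames(mat$values)])
    keep <- !is.na(mapped)
    v <- mat$values[keep, , drop = FALSE]
    ids <- mapped[keep]
    if (anyDuplicated(ids)) {
      v <- rowsum(v, ids) / as.vector(table(ids)[sort(unique(ids))])
      v <- v[order(rownames(v)), , drop = FALSE]
    } else {
      rownames(v) <- ids
    }
    matrices[[ds]] <- expression_matrix(v, ds)
  }

  associations <- NULL
  if (!is.null(paths$associations)) {
    associations <- read_association_table(pth(paths$associations))
    unmapped$associations <-
      resolve_gene_ids(associations$gene, universe)$unmapped
  }
  exclusions <- if (!is.null(paths$exclusions)) read_gmt(pth(paths$exclusions)) else list()
  age_sets <- if (!is.null(paths$age_sets)) read_gmt(pth(paths$age_sets)) else list()
  ppi <- if (!is.null(paths$ppi)) read_ppi_table(pth(paths$ppi)) else NULL
  compat <- if (!is.null(paths$compatibility)) {
    read_compatibility_matrix(pth(paths$compatibility))
  } else {
    default_compatibility_matrix()
  }
  rules <- if (!is.null(paths$layer_rules)) {
    read_layer_rules(pth(paths$layer_rules))
  } else {
    default_layer_rules()
  }

  pol <- list(
    top_frac = policies$top_frac %||% 0.01,
    upper_frac = policies$upper_frac %||% 0.25,
    middle_frac = policies$middle_frac %||% 0.50,
    lower_frac = policies$lower_frac %||% 0.25,
    drop_frac = policies$drop_frac %||% 0.05,
    z_threshold = policies$z_threshold %||% 2,
    min_conf = policies$min_conf %||% 0.5,
    channels = unlist(policies$channels) %||% c("experiments", "databases"),
    allowed_best = unlist(policies$allowed_best) %||% c("A", "B", "C"),
    seed_groups = unlist(policies$seed_groups) %||% "1a",
    seed_expr = unlist(policies$seed_expr) %||% c("A", "B")
  )
  # validate the grouping fractions eagerly
  grouping_policy(pol$top_frac, pol$upper_frac, pol$middle_frac,
    pol$lower_frac, universe_size = nrow(universe))

  file_of <- function(p) if (is.null(p)) NULL else pth(p)
  files <- c(
    list(universe = file_of(paths$universe)),
    stats::setNames(
      lapply(names(paths$expression %||% list()), function(d) pth(paths$expression[[d]])),
      paste0("expression_", names(paths$expression %||% list()))
    ),
    list(
      associations = file_of(paths$associations),
      exclusions = file_of(paths$exclusions),
      age_sets = file_of(paths$age_sets),
      ppi = file_of(paths$ppi)
    )
  )
  files <- files[!vapply(files, is.null, logical(1))]
  manifest <- list(
    row_counts = c(
      list(universe = nrow(universe)),
      stats::setNames(
        lapply(matrices, function(m) nrow(m$values)),
        paste0("expression_", names(matrices))
      ),
      list(
        associations = if (is.null(associations)) 0L else nrow(associations),
        exclusion_sets = length(exclusions),
        age_sets = length(age_sets),
        ppi_edges = if (is.null(ppi)) 0L else nrow(ppi)
      )
    ),
    unmapped_counts = lapply(unmapped, length),
    # keyed by logical table name, not by path, so manifests are
    # location-independent and reproducible across runs
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(unlist(files))), names(files)
    ))
  )
  if (!is.null(manifest_path)) yaml::write_yaml(manifest, manifest_path)

  structure(
    list(
      universe = universe, matrices = matrices, associations = associations,
      exclusions = exclusions, age_sets = age_sets, ppi = ppi,
      compat = compat, layer_rules = rules, policies = pol,
      unmapped = unmapped, manifest = manifest
    ),
    class = "rcc_bundle"
  )
}

#' @export
print.rcc_bundle <- function(x, ...) {
  cat(sprintf(
    "rcc_bundle: %d universe genes, %d expression dataset(s), %d association rows, %d PPI edges\n",
    nrow(x$universe), length(x$matrices),
    if (is.null(x$associations)) 0L else nrow(x$associations),
    if (is.null(x$ppi)) 0L else nrow(x$ppi)
  ))
  invisible(x)
}
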