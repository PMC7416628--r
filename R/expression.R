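#' Assign per-cell-type expression groups A-F
#'
#' For every cell type of a dataset, independently:
#' \enumerate{
#'   \item present genes are sorted by expression descending, ties broken
#'     by `gene_id` ascending (deterministic and input-order independent);
#'   \item the top `round_half_up(top_frac * universe_size)` \emph{expressed}
#'     genes form group `A` — the quota is tied to the universe (1% of
#'     19,300 genes = 193), never to the per-dataset gene count, and genes
#'     absent from the dataset cannot occupy quota slots;
#'   \item among the remaining expressed genes, the top `upper_frac` of
#'     their count (rounded half up) form `B`, the next `middle_frac` form
#'     `C`, and the rest form `D`;
#'   \item present genes at or below the expression floor (default 0) are
#'     `E` (non-expressed);
#'   \item universe genes absent from the dataset are `F`.
#' }
#' Matrix rows must already carry primary gene ids (see
#' [resolve_gene_ids()]); rows not in the universe are ignored and reported
#' in the `unmapped` attribute of the result.
#'
#' @param mat An `ExpressionMatrix`.
#' @param universe A `GeneUniverse`.
#' @param policy A `GroupingPolicy`; defaults to the standard
#'   1% / 25-50-25 policy over the universe size.
#' @return An `ExpressionGroupTable`: list with `dataset_id`, `groups`
#'   (character matrix, all universe genes x cell types, entries in
#'   `A`..`F`) and `present` (logical vector over the universe).
#' @export
assign_expression_groups <- function(mat, universe,
                                     policy = grouping_policy(universe_size = nrow(universe))) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(universe, "GeneUniverse"))
  if (policy$universe_size <= 0) stopf("grouping: universe_size must be positive")
  genes_u <- universe$gene_id
  in_u <- rownames(mat$values) %in% genes_u
  unmapped <- rownames(mat$values)[!in_u]
  vals <- mat$values[in_u, , drop = FALSE]

  quota <- round_half_up(policy$top_frac * policy$universe_size)
  groups <- matrix("F", nrow = length(genes_u), ncol = length(mat$cell_types),
    dimnames = list(genes_u, mat$cell_types))
  present_ids <- rownames(vals)
  row_idx <- match(present_ids, genes_u)

  for (ct in mat$cell_types) {
    v <- vals[, ct]
    expressed <- v > policy$floor
    n_expr <- sum(expressed)
    col <- rep("E", length(v))
    if (n_expr == 0L) {
      if (length(v) == 0L) warnf("cell type '%s': no genes present; column is all F", ct)
    } else {
      ord <- order(-v[expressed], present_ids[expressed])
      ranked <- which(expressed)[ord]
      n_a <- min(quota, n_expr)
      rem <- n_expr - n_a
      n_b <- min(rem, round_half_up(policy$upper_frac * rem))
      n_c <- min(rem - n_b, round_half_up(policy$middle_frac * rem))
      n_d <- rem - n_b - n_c
      col[ranked] <- rep(c("A", "B", "C", "D"), times = c(n_a, n_b, n_c, n_d))
    }
    groups[row_idx, ct] <- col
  }
  structure(
    list(
      dataset_id = mat$dataset_id,
      groups = groups,
      present = stats::setNames(genes_u %in% present_ids, genes_u)
    ),
    unmapped = unmapped,
    class = "ExpressionGroupTable"
  )
}

#' @export
print.ExpressionGroupTable <- function(x, ...) {
  cat(sprintf(
    "ExpressionGroupTable '%s': %d genes x %d cell types (%d present)\n",
    x$dataset_id, nrow(x$groups), ncol(x$groups), sum(x$present)
  ))
  invisible(x)
}

#' Best expression group per gene across datasets
#'
#' The best group is the lexicographic minimum under the ordering
#' `A < B < C < D < E < F` over every cell type of every supplied dataset;
#' genes absent everywhere are `F`.
#'
#' @param tables One `ExpressionGroupTable` or a list of them (e.g. the
#'   choroid/RPE and NR tables together, covering all 17 cell types).
#' @return Named character vector gene_id -> best group over the universe.
#' @export
best_group <- function(tables) {
  if (inherits(tables, "ExpressionGroupTable")) tables <- list(tables)
  if (!length(tables)) stopf("best_group: at least one group table required")
  genes <- rownames(tables[[1]]$groups)
  best <- rep(6L, length(genes))
  for (tab in tables) {
    stopifnot(inherits(tab, "ExpressionGroupTable"))
    if (!identical(rownames(tab$groups), genes)) {
      stopf("best_group: group tables cover different universes")
    }
    codes <- matrix(match(tab$groups, EXPRESSION_GROUPS), nrow = nrow(tab$groups))
    best <- pmin(best, apply(codes, 1, min))
  }
  stats::setNames(EXPRESSION_GROUPS[best], genes)
}

#' Cell-type specificity z-scores
#'
#' Standardizes each gene's expression across the cell types of one
#' dataset: `z = (x - mean) / sd`, with the sample (n-1) standard
#' deviation.  Rows with zero variance get `NA` (no direction of
#' specificity is defined); genes absent from the dataset do not appear.
#' Every defined row has mean 0 and sample sd 1 by construction.
#'
#' @param mat An `ExpressionMatrix` with at least two cell types.
#' @return A `SpecificityZTable`: numeric matrix genes x cell types with a
#'   `dataset_id` attribute.
#' @export
compute_zscores <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (length(mat$cell_types) < 2) {
    stopf("z-scores undefined for a single-cell-type dataset ('%s')", mat$dataset_id)
  }
  mu <- rowMeans(mat$values)
  sd <- apply(mat$values, 1, stats::sd)
  z <- (mat$values - mu) / sd
  z[sd == 0, ] <- NA_real_
  structure(z, dataset_id = mat$dataset_id, class = c("SpecificityZTable", "matrix"))
}

#' Flag cell-type-restricted expression
#'
#' A gene is flagged in a cell type when its specificity z-score meets the
#' threshold (inclusive: `z >= threshold`); undefined z-scores are never
#' flagged.
#'
#' @param z A `SpecificityZTable`.
#' @param threshold Dimensionless z threshold, default 2.
#' @return Logical matrix of the same shape.
#' @export
flag_specific <- function(z, threshold = 2.0) {
  flags <- unclass(z) >= threshold
  flags[is.na(flags)] <- FALSE
  storage.mode(flags) <- "logical"
  attr(flags, "dataset_id") <- attr(z, "dataset_id")
  flags
}

#' Write an expression-group table as long TSV
#'
#' Columns `gene_id`, `dataset`, `cell_type`, `group`.  `F` rows (absent
#' genes) are included so the written table is a total function over the
#' universe.
#'
#' @param table An `ExpressionGroupTable`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_group_table <- function(table, path) {
  g <- table$groups
  df <- data.frame(
    gene_id = rep(rownames(g), times = ncol(g)),
    dataset = table$dataset_id,
    cell_type = rep(colnames(g), each = nrow(g)),
    group = as.vector(g),
    stringsAsFactors = FALSE
  )
  write_tsv(df, path)
}

#' Write a z-score table as long TSV (defined rows only)
#' @param z A `SpecificityZTable`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_zscore_table <- function(z, path) {
  m <- unclass(z)
  df <- data.frame(
    gene_id = rep(rownames(m), times = ncol(m)),
    dataset = attr(z, "dataset_id") %||% NA_character_,
    cell_type = rep(colnames(m), each = nrow(m)),
    z = as.vector(m),
    stringsAsFactors = FALSE
  )
  write_tsv(df[!is.na(df$z), , drop = FALSE], path)
}
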