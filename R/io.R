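#' Construct an expression matrix for one dataset
#'
#' Holds averaged (per-cell-type mean over single cells) nonnegative
#' expression values for one dataset, genes in rows and cell types in
#' columns.  Row names are raw gene names until resolved against the
#' universe; genes absent from the matrix are later classed `F`.
#'
#' @param values Numeric matrix, genes x cell types, with rownames and
#'   unique colnames; all values must be >= 0 and non-missing.
#' @param dataset_id One of `"choroid_rpe"`, `"nr"`, `"tissue"` (or any
#'   other label for ad-hoc datasets).
#' @return An `ExpressionMatrix` (list with `dataset_id`, `cell_types`,
#'   `values`).
#' @export
expression_matrix <- function(values, dataset_id) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stopf("expression matrix '%s': rownames (gene ids) required", dataset_id)
  if (is.null(colnames(values))) stopf("expression matrix '%s': colnames (cell types) required", dataset_id)
  if (anyDuplicated(colnames(values))) {
    stopf("expression matrix '%s': duplicated cell-type column(s)", dataset_id)
  }
  if (anyDuplicated(rownames(values))) {
    stopf("expression matrix '%s': duplicated gene row(s)", dataset_id)
  }
  if (anyNA(values)) stopf("expression matrix '%s': missing values are not allowed", dataset_id)
  if (any(values < 0)) stopf("expression matrix '%s': negative expression value(s)", dataset_id)
  structure(
    list(dataset_id = dataset_id, cell_types = colnames(values), values = values),
    class = "ExpressionMatrix"
  )
}

#' Read an expression matrix from TSV
#'
#' First column is the gene identifier, remaining columns are one per cell
#' type.
#'
#' @param path Path to the TSV.
#' @param dataset_id Dataset label stored on the returned object.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, dataset_id) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2) stopf("expression matrix '%s': needs a gene column plus >=1 cell type", path)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- genes
  expression_matrix(mat, dataset_id)
}

#' Write an expression matrix to TSV
#' @param mat An `ExpressionMatrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  write_matrix_tsv(mat$values, path)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix '%s': %d genes x %d cell types\n",
    x$dataset_id, nrow(x$values), length(x$cell_types)
  ))
  invisible(x)
}

#' Merge cell clusters into one cell type
#'
#' Collapses sub-clusters of one biological cell type (for instance two
#' Schwann-cell clusters in the choroid/RPE dataset) into a single column.
#' The merged column is the unweighted arithmetic mean of the member
#' cluster columns; per-cluster cell counts are not part of the input, so
#' no weighting is attempted.
#'
#' @param mat An `ExpressionMatrix`.
#' @param merge_map Named character vector: names are existing columns,
#'   values are the merged cell-type label.  Columns sharing a value are
#'   averaged; columns not named are kept unchanged.
#' @return An `ExpressionMatrix` with merged columns (merged columns appear
#'   at the position of their first member).
#' @export
merge_cell_clusters <- function(mat, merge_map) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!length(merge_map)) return(mat)
  if (is.null(names(merge_map))) stopf("merge_map must be a named character vector (cluster -> cell type)")
  absent <- setdiff(names(merge_map), mat$cell_types)
  if (length(absent)) {
    stopf("merge_map references missing column(s): %s", paste(absent, collapse = ", "))
  }
  target <- ifelse(mat$cell_types %in% names(merge_map),
    merge_map[mat$cell_types], mat$cell_types)
  new_cols <- unique(target)
  out <- vapply(new_cols, function(ct) {
    rowMeans(mat$values[, target == ct, drop = FALSE])
  }, numeric(nrow(mat$values)))
  rownames(out) <- rownames(mat$values)
  colnames(out) <- new_cols
  expression_matrix(out, mat$dataset_id)
}

#' Grouping policy for expression classes
#'
#' @param top_frac Fraction of the universe forming the group-A quota
#'   (default 0.01: the top 1% of 19,300 genes is 193).
#' @param upper_frac,middle_frac,lower_frac Fractions of the remaining
#'   expressed genes assigned to groups B, C and D (defaults 0.25/0.50/0.25;
#'   must sum to 1).
#' @param universe_size Gene count the group-A quota is computed from.
#' @param floor Expression value at or below which a present gene counts as
#'   non-expressed (group E).  Default 0: "expressed" means strictly
#'   positive.
#' @return A `GroupingPolicy` list.
#' @export
grouping_policy <- function(top_frac = 0.01, upper_frac = 0.25,
                            middle_frac = 0.50, lower_frac = 0.25,
                            universe_size, floor = 0) {
  fr <- c(top_frac, upper_frac, middle_frac, lower_frac)
  if (any(fr < 0 | fr > 1)) stopf("grouping policy: fractions must lie in [0, 1]")
  if (abs(upper_frac + middle_frac + lower_frac - 1) > 1e-12) {
    stopf("grouping policy: upper + middle + lower fractions must sum to 1")
  }
  if (missing(universe_size) || universe_size <= 0) {
    stopf("grouping policy: universe_size must be a positive count")
  }
  structure(
    list(
      top_frac = top_frac, upper_frac = upper_frac, middle_frac = middle_frac,
      lower_frac = lower_frac, universe_size = as.integer(universe_size),
      floor = floor
    ),
    class = "GroupingPolicy"
  )
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (unique members, empty members
#'   dropped), with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stopf("GMT parse error at line %d: expected name, description and >=1 member", line_no[i])
    }
    nm <- f[1]
    if (nm %in% names(sets)) stopf("GMT: duplicated set name '%s' (line %d)", nm, line_no[i])
    members <- unique(f[-(1:2)])
    members <- members[members != ""]
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  structure(sets, descriptions = desc, class = c("GeneSetCollection", "list"))
}

#' Write a gene-set collection to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease-gene association table from TSV
#'
#' Columns `gene`, `disease_id`, `score`; scores are association strengths
#' in `[0, 1]` (1 = strongest).  `(gene, disease_id)` pairs must be unique;
#' the same underlying gene may still appear under both its primary symbol
#' and an alias, which downstream pruning reconciles by keeping the
#' maximum score.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame with class `AssociationTable`.
#' @export
read_association_table <- function(path) {
  df <- read_tsv_strict(path)
  association_table(df)
}

#' @rdname read_association_table
#' @param df A data.frame with columns `gene`, `disease_id`, `score`.
#' @export
association_table <- function(df) {
  need <- c("gene", "disease_id", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("association table: missing column(s): %s", paste(miss, collapse = ", "))
  df$score <- as.numeric(df$score)
  if (anyNA(df$score) || any(df$score < 0 | df$score > 1)) {
    stopf("association table: scores must lie in [0, 1]")
  }
  key <- paste(df$gene, df$disease_id, sep = "\r")
  if (anyDuplicated(key)) {
    stopf("association table: duplicated (gene, disease_id) pair(s), e.g. %s",
      df$gene[duplicated(key)][1])
  }
  class(df) <- c("AssociationTable", "data.frame")
  df
}

#' Read a PPI edge table from TSV
#'
#' Columns `protein_a`, `protein_b`, `confidence` (in `[0, 1]`),
#' `channels` (comma-delimited subset of [PPI_CHANNELS]).  On load, edges
#' are made undirected-canonical (`a = min`, `b = max` lexicographically),
#' self-loops are dropped, and duplicated edges are collapsed keeping the
#' maximum confidence and the union of channels.
#'
#' @param path Path to the TSV.
#' @return A validated data.frame with class `PPIEdgeTable`.
#' @export
read_ppi_table <- function(path) {
  ppi_edge_table(read_tsv_strict(path))
}

#' @rdname read_ppi_table
#' @param df Data.frame with the four PPI columns.
#' @export
ppi_edge_table <- function(df) {
  need <- c("protein_a", "protein_b", "confidence", "channels")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("PPI table: missing column(s): %s", paste(miss, collapse = ", "))
  df$confidence <- as.numeric(df$confidence)
  if (anyNA(df$confidence) || any(df$confidence < 0 | df$confidence > 1)) {
    stopf("PPI table: confidence must lie in [0, 1]")
  }
  chan <- strsplit(ifelse(is.na(df$channels), "", df$channels), ",", fixed = TRUE)
  bad <- setdiff(unique(trimws(unlist(chan))), c(PPI_CHANNELS, ""))
  if (length(bad)) {
    stopf("PPI table: unknown evidence channel(s): %s", paste(bad, collapse = ", "))
  }
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  keep <- a != b
  df <- data.frame(
    protein_a = a[keep], protein_b = b[keep],
    confidence = df$confidence[keep],
    channels = vapply(chan[keep], function(x) {
      paste(sort(unique(trimws(x[x != ""]))), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  key <- paste(df$protein_a, df$protein_b, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$confidence)
    df <- df[ord, , drop = FALSE]
    key <- key[ord]
    # union channels within duplicate groups, keep max confidence (first row)
    ch_union <- tapply(df$channels, key, function(x) {
      paste(sort(unique(unlist(strsplit(x, ",", fixed = TRUE)))), collapse = ",")
    })
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$channels <- unname(ch_union[paste(df$protein_a, df$protein_b, sep = "\r")])
  }
  rownames(df) <- NULL
  class(df) <- c("PPIEdgeTable", "data.frame")
  df
}

#' Write a PPI edge table to TSV
#' @param ppi A `PPIEdgeTable`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ppi_table <- function(ppi, path) {
  write_tsv(as.data.frame(ppi), path)
}
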