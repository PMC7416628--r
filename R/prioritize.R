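#' Default tissue-specificity tier map
#'
#' Maps cross-tissue distribution classes onto three tiers: `specific`
#' (detected in some/single tissues or not detected outside the target
#' tissue), `intermediate` (detected in many) and `generic` (detected in
#' all).  Genes with no distribution information default to `generic`
#' (the conservative choice: missing evidence of restriction is not
#' evidence of restriction).  The map is configurable because the
#' published grouping can be read in more than one way.
#'
#' @return Named character vector class -> tier, plus an `na_tier`
#'   attribute for `NA` classes.
#' @export
default_tier_map <- function() {
  structure(
    c(
      "Detected in some" = "specific",
      "Detected in single" = "specific",
      "Not detected" = "specific",
      "Detected in many" = "intermediate",
      "Detected in all" = "generic"
    ),
    na_tier = "generic"
  )
}

tier_of <- function(tissue_distribution, tier_map = default_tier_map()) {
  na_tier <- attr(tier_map, "na_tier") %||% "generic"
  out <- unname(tier_map[tissue_distribution])
  out[is.na(tissue_distribution)] <- na_tier
  if (anyNA(out)) {
    stopf("tier map does not cover tissue class(es): %s",
      paste(unique(tissue_distribution[is.na(out) & !is.na(tissue_distribution)]),
        collapse = ", "))
  }
  out
}

#' Prune a raw disease association list
#'
#' Applies, in this order: (1) keep only genes that resolve to the
#' protein-coding universe (rows under aliases are mapped to their primary
#' symbol; a gene reached by several raw names keeps its maximum score);
#' (2) remove members of any exclusion set (e.g. genes of early-onset
#' phenocopy degenerations); (3) remove the `floor(drop_frac * n)`
#' lowest-scoring remaining genes, ties at the boundary resolved by score
#' ascending then `gene_id` ascending.  The order matters and is part of
#' the contract: the bottom-quantile is computed on the post-exclusion
#' list.
#'
#' @param assoc An `AssociationTable`.
#' @param universe A `GeneUniverse`.
#' @param exclusions A `GeneSetCollection` (members may be raw names; they
#'   are resolved against the universe, unresolvable members ignored).
#' @param drop_frac Fraction of lowest-scoring genes to drop, in `[0, 1)`.
#' @return Data.frame `gene_id`, `score`, sorted by score descending then
#'   gene_id; attributes `n_input`, `n_coding`, `n_post_exclusion`,
#'   `unmapped`.
#' @export
prune_risk_genes <- function(assoc, universe, exclusions = list(),
                             drop_frac = 0.05) {
  stopifnot(inherits(universe, "GeneUniverse"))
  if (drop_frac < 0 || drop_frac >= 1) stopf("drop_frac must lie in [0, 1)")
  res <- resolve_gene_ids(assoc$gene, universe)
  gene_id <- unname(res$mapping[assoc$gene])
  ok <- !is.na(gene_id)
  df <- data.frame(gene_id = gene_id[ok], score = assoc$score[ok],
    stringsAsFactors = FALSE)
  # max score per resolved gene
  df <- df[order(df$gene_id, -df$score), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  n_coding <- nrow(df)

  excl_ids <- character(0)
  if (length(exclusions)) {
    excl_raw <- unique(unlist(exclusions, use.names = FALSE))
    excl_ids <- unname(resolve_gene_ids(excl_raw, universe)$mapping)
  }
  df <- df[!df$gene_id %in% excl_ids, , drop = FALSE]
  n_post_exclusion <- nrow(df)

  n_drop <- floor(drop_frac * n_post_exclusion)
  if (n_drop > 0) {
    ord <- order(df$score, df$gene_id)
    df <- df[-ord[seq_len(n_drop)], , drop = FALSE]
  }
  df <- df[order(-df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    n_input = length(unique(assoc$gene)), n_coding = n_coding,
    n_post_exclusion = n_post_exclusion, unmapped = res$unmapped
  )
}

#' Keep high-confidence risk genes by expression class
#'
#' Retains genes whose best expression group across all cell types of all
#' datasets falls in `allowed` (default `A`, `B`, `C`: expressed at least
#' at the middle-50% level in at least one cell type).
#'
#' @param pruned Data.frame from [prune_risk_genes()] (columns `gene_id`,
#'   `score`).
#' @param best Named character vector gene_id -> best group (see
#'   [best_group()]).
#' @param allowed Set of admissible best groups.
#' @return The filtered data.frame with a `best_group` column.
#' @export
filter_high_confidence <- function(pruned, best, allowed = c("A", "B", "C")) {
  bg <- unname(best[pruned$gene_id])
  bg[is.na(bg)] <- "F"
  out <- pruned[bg %in% allowed, , drop = FALSE]
  out$best_group <- bg[bg %in% allowed]
  rownames(out) <- NULL
  out
}

#' Assign tissue-specificity groups 1a/1b/2/3
#'
#' Risk genes are tiered by how broadly they are expressed across body
#' tissues, then split by involvement in other age-related diseases:
#' tier `specific` without any age-disease membership is group `1a`
#' (tissue-restricted, disease-private); `specific` with membership in at
#' least one age-disease set is `1b`; tier `intermediate` is group `2` and
#' tier `generic` group `3` (both regardless of age-disease overlap).
#' The four groups partition the input list.
#'
#' @param genes Character vector of gene ids (the high-confidence list).
#' @param universe A `GeneUniverse`.
#' @param age_sets A `GeneSetCollection` of other age-related disease gene
#'   sets (members resolved against the universe).
#' @param tier_map Tier map, see [default_tier_map()].
#' @return Named character vector gene_id -> group in `{1a, 1b, 2, 3}`.
#' @export
assign_specificity_groups <- function(genes, universe, age_sets = list(),
                                      tier_map = default_tier_map()) {
  stopifnot(inherits(universe, "GeneUniverse"))
  idx <- match(genes, universe$gene_id)
  if (anyNA(idx)) {
    stopf("gene(s) missing from the universe: %s",
      paste(utils::head(genes[is.na(idx)], 5), collapse = ", "))
  }
  tiers <- tier_of(universe$tissue_distribution[idx], tier_map)
  n_other <- disease_overlap_counts(genes, universe, age_sets)
  grp <- ifelse(tiers == "generic", "3",
    ifelse(tiers == "intermediate", "2",
      ifelse(n_other >= 1, "1b", "1a")))
  stats::setNames(grp, genes)
}

disease_overlap_counts <- function(genes, universe, age_sets) {
  counts <- stats::setNames(integer(length(genes)), genes)
  for (s in age_sets) {
    ids <- unname(resolve_gene_ids(s, universe)$mapping)
    counts <- counts + as.integer(genes %in% ids)
  }
  counts
}

#' Overlap of risk genes with other age-related disease sets
#'
#' @param genes Character vector of gene ids.
#' @param universe A `GeneUniverse`.
#' @param age_sets A `GeneSetCollection`.
#' @param top_k How many top-overlap genes to rank (count descending, then
#'   gene_id ascending).
#' @return List with `counts` (named integer, per-gene number of disease
#'   sets containing the gene), `overlap_fraction` (share of genes with
#'   count >= 1) and `ranking` (data.frame of the top `top_k`).
#' @export
disease_overlap_summary <- function(genes, universe, age_sets, top_k = 5) {
  counts <- disease_overlap_counts(genes, universe, age_sets)
  frac <- if (length(counts)) mean(counts >= 1) else 0
  ord <- order(-counts, names(counts))
  ranking <- data.frame(
    gene_id = names(counts)[ord], n_other_diseases = unname(counts[ord]),
    stringsAsFactors = FALSE
  )[seq_len(min(top_k, length(counts))), , drop = FALSE]
  rownames(ranking) <- NULL
  list(counts = counts, overlap_fraction = frac, ranking = ranking)
}

#' Assemble the full risk-gene record table
#'
#' One row per pruned risk gene: association score, best expression group,
#' tissue-specificity group (`NA` unless the gene passed the
#' high-confidence filter) and the number of other age-related disease
#' sets it belongs to.
#'
#' @inheritParams assign_specificity_groups
#' @param pruned Output of [prune_risk_genes()].
#' @param best Named best-group vector from [best_group()].
#' @param allowed Best groups admitted to the high-confidence list.
#' @return Data.frame with class `RiskGeneTable`: columns `gene_id`,
#'   `score`, `best_group`, `specificity_group`, `n_other_diseases`.
#' @export
risk_gene_records <- function(pruned, best, universe, age_sets = list(),
                              tier_map = default_tier_map(),
                              allowed = c("A", "B", "C")) {
  hc <- filter_high_confidence(pruned, best, allowed)
  spec <- assign_specificity_groups(hc$gene_id, universe, age_sets, tier_map)
  bg <- unname(best[pruned$gene_id])
  bg[is.na(bg)] <- "F"
  df <- data.frame(
    gene_id = pruned$gene_id,
    score = pruned$score,
    best_group = bg,
    specificity_group = unname(spec[pruned$gene_id]),
    n_other_diseases = unname(disease_overlap_counts(pruned$gene_id, universe, age_sets)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("RiskGeneTable", "data.frame")
  df
}
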