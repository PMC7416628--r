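#' Construct and validate a gene universe
#'
#' The gene universe is the fixed background of protein-coding genes against
#' which everything downstream is resolved: expression matrices, association
#' tables, gene sets, PPI nodes and enrichment backgrounds.  Each gene
#' carries a primary symbol, a set of aliases, a one-gene-one-class
#' functional ontology label at three granularities (`sysgo_set1` ~321
#' classes, `sysgo_set2` ~58 groups, `sysgo_set3` 15 broad labels), a
#' predominant subcellular localization at three granularities
#' (`loc_set1`/`loc_set2`/`loc_set3`, 47/39/8-level schemes, `NA` allowed)
#' and a cross-tissue distribution class (see [TISSUE_CLASSES]).
#'
#' Validation enforces: unique `gene_id`s; no alias pointing at two distinct
#' genes; tissue-distribution values drawn from the enumerated classes; and
#' that `sysgo_set3` is a deterministic function of `sysgo_set2` (each set-2
#' group maps to exactly one set-3 label).
#'
#' @param df A data.frame with columns `gene_id`, `aliases` (pipe-delimited
#'   string, may be empty/`NA`), `sysgo_set1`, `sysgo_set2`, `sysgo_set3`,
#'   `loc_set1`, `loc_set2`, `loc_set3`, `tissue_distribution`.
#' @return A `GeneUniverse`: the validated data.frame with an `alias_map`
#'   attribute (named character vector alias -> gene_id).
#' @seealso [read_gene_universe()], [resolve_gene_ids()]
#' @export
gene_universe <- function(df) {
  required <- c(
    "gene_id", "aliases", "sysgo_set1", "sysgo_set2", "sysgo_set3",
    "loc_set1", "loc_set2", "loc_set3", "tissue_distribution"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stopf("universe table is missing column(s): %s",
      paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  if (anyNA(df$gene_id) || any(df$gene_id == "")) {
    stopf("universe: gene_id must be non-missing and non-empty")
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stopf("universe: duplicated gene_id(s): %s",
      paste(utils::head(dup, 5), collapse = ", "))
  }
  bad_td <- setdiff(unique(df$tissue_distribution[!is.na(df$tissue_distribution)]),
    TISSUE_CLASSES)
  if (length(bad_td)) {
    stopf("universe: tissue_distribution value(s) outside the enumerated classes: %s",
      paste(bad_td, collapse = ", "))
  }

  # set3 must be a function of set2
  ok <- !is.na(df$sysgo_set2)
  if (any(ok)) {
    m <- tapply(df$sysgo_set3[ok], df$sysgo_set2[ok],
      function(x) length(unique(x)))
    off <- names(m)[m > 1]
    if (length(off)) {
      stopf("universe: sysgo_set2 group(s) mapping to more than one sysgo_set3 label: %s",
        paste(utils::head(off, 5), collapse = ", "))
    }
  }

  alias_map <- build_alias_map(df)
  structure(df, alias_map = alias_map, class = c("GeneUniverse", "data.frame"))
}

# Named vector alias -> gene_id; errors (naming the alias) when one alias
# points at two distinct genes.
build_alias_map <- function(df) {
  al <- df$aliases
  al[is.na(al)] <- ""
  parts <- strsplit(al, "|", fixed = TRUE)
  n_each <- lengths(parts)
  alias <- unlist(parts, use.names = FALSE)
  owner <- rep(df$gene_id, n_each)
  keep <- !is.na(alias) & alias != ""
  alias <- alias[keep]
  owner <- owner[keep]
  if (!length(alias)) {
    return(stats::setNames(character(0), character(0)))
  }
  # an alias repeated under the same gene is harmless; across genes it is not
  key <- paste(alias, owner, sep = "\r")
  first <- !duplicated(key)
  alias <- alias[first]
  owner <- owner[first]
  dup <- unique(alias[duplicated(alias)])
  if (length(dup)) {
    stopf("universe: alias mapped to two distinct gene_ids: %s",
      paste(utils::head(dup, 5), collapse = ", "))
  }
  stats::setNames(owner, alias)
}

#' Read a gene universe table from TSV
#'
#' @param path Path to a tab-separated universe table with a header row;
#'   `#` comment lines are ignored.  Columns as in [gene_universe()].
#' @return A validated `GeneUniverse`.
#' @export
read_gene_universe <- function(path) {
  df <- read_tsv_strict(path)
  if ("aliases" %in% names(df)) {
    df$aliases[is.na(df$aliases)] <- ""
  }
  gene_universe(df)
}

#' Write a gene universe table to TSV
#'
#' Inverse of [read_gene_universe()]; write-then-read round-trips exactly.
#'
#' @param universe A `GeneUniverse`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_universe <- function(universe, path) {
  df <- as.data.frame(universe)
  write_tsv(df, path)
}

#' Resolve raw gene names against the universe
#'
#' Maps each raw name to at most one primary `gene_id`.  An exact primary
#' symbol match wins over an alias match; resolution is case-sensitive
#' unless `case_insensitive = TRUE` (human symbols are uppercase, and case
#' is meaningful across species).  Resolution is deterministic and
#' idempotent: resolving already-resolved ids changes nothing.
#'
#' @param raw_names Character vector of raw gene names (duplicates allowed).
#' @param universe A `GeneUniverse`.
#' @param case_insensitive Match ignoring case (both primaries and aliases)?
#' @return A list with `mapping` (named character vector raw -> gene_id for
#'   the resolvable names, in first-appearance order), `unmapped` (unique
#'   unresolvable names) and `n_unmapped`.
#' @export
resolve_gene_ids <- function(raw_names, universe, case_insensitive = FALSE) {
  stopifnot(inherits(universe, "GeneUniverse"))
  raw_names <- as.character(raw_names)
  raw <- unique(raw_names[!is.na(raw_names) & raw_names != ""])
  alias_map <- attr(universe, "alias_map")
  primaries <- universe$gene_id
  if (case_insensitive) {
    hit_p <- match(toupper(raw), toupper(primaries))
    hit_a <- match(toupper(raw), toupper(names(alias_map)))
  } else {
    hit_p <- match(raw, primaries)
    hit_a <- match(raw, names(alias_map))
  }
  mapped <- ifelse(!is.na(hit_p), primaries[hit_p],
    ifelse(!is.na(hit_a), unname(alias_map)[hit_a], NA_character_))
  ok <- !is.na(mapped)
  list(
    mapping = stats::setNames(mapped[ok], raw[ok]),
    unmapped = raw[!ok],
    n_unmapped = sum(!ok)
  )
}
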