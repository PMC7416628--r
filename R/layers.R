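#' Compartment compatibility matrix
#'
#' Two proteins can physically interact only if their subcellular
#' compartments can meet: an extracellular protein cannot touch a cytosolic
#' one.  The matrix is symmetric over the 8-level localization scheme
#' (`loc_set3`); same-compartment pairs are always allowed and any pair not
#' explicitly disallowed is allowed.
#'
#' @param compartments Character vector of compartment labels.
#' @param disallowed List of length-2 character vectors (unordered pairs)
#'   that are incompatible.  Same-compartment pairs may not be disallowed.
#' @return A `CompatibilityMatrix`: logical matrix with dimnames.
#' @export
compatibility_matrix <- function(compartments, disallowed = list()) {
  compartments <- unique(as.character(compartments))
  m <- matrix(TRUE, length(compartments), length(compartments),
    dimnames = list(compartments, compartments))
  for (p in disallowed) {
    if (length(p) != 2) stopf("compatibility matrix: disallowed entries must be pairs")
    if (!all(p %in% compartments)) {
      stopf("compatibility matrix: unknown compartment in pair (%s, %s)", p[1], p[2])
    }
    if (p[1] == p[2]) stopf("compatibility matrix: same-compartment pairs are always allowed (%s)", p[1])
    m[p[1], p[2]] <- FALSE
    m[p[2], p[1]] <- FALSE
  }
  structure(m, class = c("CompatibilityMatrix", "matrix"))
}

#' Default 8-compartment localization scheme
#' @return Character vector of the 8 `loc_set3` labels.
#' @export
loc_set3_levels <- function() {
  c(
    "Extracellular", "Plasma membrane", "Cytosol", "Nucleus",
    "Mitochondria", "Endomembrane system", "Vesicles and lysosomes",
    "Cytoskeleton"
  )
}

#' Default compartment compatibility matrix
#'
#' Extracellular proteins are incompatible with cytosolic, nuclear,
#' mitochondrial and cytoskeletal partners (compartments separated by at
#' least one membrane with no shared lumen).  Plasma-membrane proteins are
#' compatible with both extracellular and cytosolic partners (they span the
#' bilayer).  Everything else, including every same-compartment pair, is
#' allowed.  The matrix ships as an editable YAML
#' (`system.file("extdata", "compatibility_matrix.yaml", package = "rccnet")`).
#'
#' @return A `CompatibilityMatrix`.
#' @export
default_compatibility_matrix <- function() {
  compatibility_matrix(
    loc_set3_levels(),
    disallowed = list(
      c("Extracellular", "Cytosol"),
      c("Extracellular", "Nucleus"),
      c("Extracellular", "Mitochondria"),
      c("Extracellular", "Cytoskeleton")
    )
  )
}

#' Read / write a compatibility matrix as YAML
#'
#' YAML layout: `compartments:` (list) and `disallowed:` (list of pairs).
#'
#' @param path YAML path.
#' @return [read_compatibility_matrix()]: a `CompatibilityMatrix`.
#' @export
read_compatibility_matrix <- function(path) {
  y <- yaml::read_yaml(path)
  compatibility_matrix(unlist(y$compartments),
    disallowed = lapply(y$disallowed, unlist))
}

#' @rdname read_compatibility_matrix
#' @param compat A `CompatibilityMatrix`.
#' @return [write_compatibility_matrix()]: the path, invisibly.
#' @export
write_compatibility_matrix <- function(compat, path) {
  labs <- rownames(compat)
  dis <- list()
  for (i in seq_along(labs)) {
    for (j in seq_len(i - 1L)) {
      if (!compat[i, j]) dis[[length(dis) + 1L]] <- c(labs[j], labs[i])
    }
  }
  yaml::write_yaml(list(compartments = labs, disallowed = dis), path)
  invisible(path)
}

#' Anatomical-layer rule set
#'
#' Nodes of a subnetwork are stratified into six anatomical layers (AL1
#' systemic/immune ... AL6 intracellular/nuclear) by an ordered rule
#' engine: explicit per-gene overrides take precedence, then the first
#' matching rule wins, then the default.  Rules predicate on the node's
#' functional group (`sysgo_set2`), broad class (`sysgo_set3`) or
#' compartment (`loc_set3`).
#'
#' @param rules List of rules, each a list with `field` (one of
#'   `"sysgo_set2"`, `"sysgo_set3"`, `"loc_set3"`), `values` (character) and
#'   `layer` (one of [ANATOMICAL_LAYERS]).
#' @param overrides Named character vector gene_id -> layer.
#' @param default Layer used when nothing matches, or `"unassigned"`.
#' @return A `LayerRuleSet`.
#' @export
layer_rules <- function(rules = list(), overrides = character(0),
                        default = "unassigned") {
  ok_fields <- c("sysgo_set2", "sysgo_set3", "loc_set3")
  ok_layers <- c(ANATOMICAL_LAYERS, "unassigned")
  for (r in rules) {
    if (!all(c("field", "values", "layer") %in% names(r))) {
      stopf("layer rule missing field/values/layer")
    }
    if (!r$field %in% ok_fields) stopf("layer rule: unknown field '%s'", r$field)
    if (!r$layer %in% ok_layers) stopf("layer rule: unknown layer '%s'", r$layer)
  }
  overrides <- unlist(overrides) %||% character(0)
  if (length(overrides)) {
    bad <- setdiff(unique(overrides), ok_layers)
    if (length(bad)) stopf("layer overrides: unknown layer(s): %s", paste(bad, collapse = ", "))
  }
  if (!default %in% ok_layers) stopf("layer rules: unknown default layer '%s'", default)
  structure(list(rules = rules, overrides = overrides, default = default),
    class = "LayerRuleSet")
}

#' Default anatomical-layer rules
#'
#' A transparent approximation of the layered anatomy: immune/inflammation
#' classes go to AL1, ECM organization to AL2, cell junction/adhesion to
#' AL3, remaining extracellular or plasma-membrane proteins to AL4
#' (cell-surface signaling), metabolic classes to AL5, and remaining
#' intracellular compartments to AL6.  Because published layer placements
#' also drew on manual curation, a shipped override file
#' (`system.file("extdata", "seed_layer_overrides.yaml", package = "rccnet")`)
#' can pin individual genes to layers regardless of the rules.
#'
#' @return A `LayerRuleSet`.
#' @export
default_layer_rules <- function() {
  layer_rules(
    rules = list(
      list(field = "sysgo_set3", values = "Immune system and Inflammation", layer = "AL1"),
      list(field = "sysgo_set3", values = "ECM organization", layer = "AL2"),
      list(field = "sysgo_set3", values = "Cell junction and adhesion", layer = "AL3"),
      list(field = "loc_set3", values = c("Extracellular", "Plasma membrane"), layer = "AL4"),
      list(field = "sysgo_set3", values = "Metabolism", layer = "AL5"),
      list(
        field = "loc_set3",
        values = c(
          "Cytosol", "Nucleus", "Mitochondria", "Endomembrane system",
          "Vesicles and lysosomes", "Cytoskeleton"
        ),
        layer = "AL6"
      )
    ),
    default = "unassigned"
  )
}

#' Read / write a layer rule set as YAML
#' @param path YAML path with keys `rules`, `overrides`, `default`.
#' @return [read_layer_rules()]: a `LayerRuleSet`.
#' @export
read_layer_rules <- function(path) {
  y <- yaml::read_yaml(path)
  ov <- unlist(y$overrides) %||% character(0)
  layer_rules(
    rules = lapply(y$rules, function(r) {
      list(field = r$field, values = unlist(r$values), layer = r$layer)
    }),
    overrides = ov,
    default = y$default %||% "unassigned"
  )
}

#' @rdname read_layer_rules
#' @param rules A `LayerRuleSet`.
#' @return [write_layer_rules()]: the path, invisibly.
#' @export
write_layer_rules <- function(rules, path) {
  yaml::write_yaml(
    list(
      rules = rules$rules,
      overrides = as.list(rules$overrides),
      default = rules$default
    ),
    path
  )
  invisible(path)
}
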