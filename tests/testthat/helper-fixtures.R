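# Fixtures and independent oracles, all built in code.

# Minimal universe: ids (+ optional aliases / annotations) with defaults.
toy_universe <- function(ids, aliases = NULL, sysgo_set2 = NULL,
                         sysgo_set3 = NULL, loc_set3 = NULL,
                         tissue = NULL) {
  n <- length(ids)
  s3 <- sysgo_set3 %||% rep("s1", n)
  s2 <- sysgo_set2 %||% (if (is.null(sysgo_set3)) rep("g1", n) else s3)
  gene_universe(data.frame(
    gene_id = ids,
    aliases = aliases %||% rep("", n),
    sysgo_set1 = s2,
    sysgo_set2 = s2,
    sysgo_set3 = s3,
    loc_set1 = loc_set3 %||% rep(NA_character_, n),
    loc_set2 = loc_set3 %||% rep(NA_character_, n),
    loc_set3 = loc_set3 %||% rep(NA_character_, n),
    tissue_distribution = tissue %||% rep(NA_character_, n),
    stringsAsFactors = FALSE
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_matrix <- function(values, genes, cell_types, dataset = "choroid_rpe") {
  m <- matrix(values, nrow = length(genes), ncol = length(cell_types),
    dimnames = list(genes, cell_types))
  expression_matrix(m, dataset)
}

# Independent grouping oracle: full sort plus explicit cut indices.
oracle_groups <- function(values, genes, universe_size,
                          top_frac = 0.01, upper_frac = 0.25,
                          middle_frac = 0.50) {
  stopifnot(length(values) == length(genes))
  out <- setNames(rep("E", length(genes)), genes)
  expressed <- which(values > 0)
  if (length(expressed)) {
    ord <- expressed[order(-values[expressed], genes[expressed])]
    quota <- floor(top_frac * universe_size + 0.5)
    n_a <- min(quota, length(ord))
    rem <- length(ord) - n_a
    n_b <- min(rem, floor(upper_frac * rem + 0.5))
    n_c <- min(rem - n_b, floor(middle_frac * rem + 0.5))
    lab <- rep(c("A", "B", "C", "D"), c(n_a, n_b, n_c, rem - n_b - n_c))
    out[genes[ord]] <- lab
  }
  out
}

# Hypergeometric upper-tail enumeration from binomial coefficients.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- seq(k, min(n, K))
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Universe of N genes with one annotated class of size K (rest "other"),
# used to drive fisher_enrichment end-to-end on small tables.
enrich_universe <- function(N, K) {
  toy_universe(sprintf("g%03d", seq_len(N)),
    sysgo_set2 = rep(c("classX", "other"), c(K, N - K)))
}

# A small but complete synthetic bundle for integration tests.
small_config <- function(seed = 42, ...) {
  synthetic_config(
    seed = seed, n_genes = 4000, n_risk = 160, n_seeds = 10,
    interactors_per_seed = 5, background_nodes = 250,
    background_edges = 500, age_set_size = 100,
    exclusion_set_size = 15, exclusion_risk_overlap = 10, ...
  )
}
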