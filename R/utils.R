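# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Quota and cut sizes use arithmetic half-up rounding (0.5 rounds up),
#' not the IEEE round-half-even of [base::round()], so that cut points are
#' reproducible across platforms and match the documented grouping rule.
#'
#' @param x Numeric vector (nonnegative in all internal uses).
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Deterministic child seed for a named stream, derived from one root seed.
# Adding a new stream never perturbs existing streams.
child_seed <- function(root, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 131L) %% 1000003L
  as.integer((as.double(root) + h * 7919) %% 2147483563)
}

# Evaluate `expr` under a temporary RNG state seeded from (root, stream).
with_stream_seed <- function(root, stream, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(child_seed(root, stream))
  expr
}

# Strict TSV reader: tab-separated, header row, '#' comment lines ignored,
# no quoting, never factors.
read_tsv_strict <- function(path, ...) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  utils::read.delim(path,
    sep = "\t", header = TRUE, comment.char = "#", quote = "",
    stringsAsFactors = FALSE, check.names = FALSE, na.strings = c("NA", ""),
    ...
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

# Format a numeric matrix (genes x cell types) as a TSV with a gene_id key.
write_matrix_tsv <- function(mat, path, key = "gene_id") {
  df <- data.frame(rownames(mat), mat,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df)[1] <- key
  write_tsv(df, path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
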