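# internal helpers shared across modules

# assert that `df` has the named columns; error names the missing ones
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# ensure a pair table carries a stable pair_id; derived ids are copy1|copy2
ensure_pair_id <- function(pairs) {
  check_columns(pairs, c("copy1", "copy2"), "pairs")
  if (!"pair_id" %in% names(pairs)) {
    pairs <- dplyr::mutate(pairs,
                           pair_id = paste(.data$copy1, .data$copy2, sep = "|"),
                           .before = 1)
  }
  if (anyDuplicated(pairs$pair_id)) {
    abort("pairs has duplicated pair_id values")
  }
  if (any(pairs$copy1 == pairs$copy2)) {
    abort("pairs contains a pair whose two copies are the same gene")
  }
  pairs
}

# expression tibble (gene + tissue columns) -> numeric matrix with rownames
expression_matrix <- function(expr) {
  check_columns(expr, "gene", "expression")
  if (anyDuplicated(expr$gene)) abort("expression has duplicated gene identifiers")
  tissues <- setdiff(names(expr), "gene")
  if (anyDuplicated(tissues)) abort("expression has duplicated tissue labels")
  m <- as.matrix(expr[tissues])
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (any(m < 0, na.rm = TRUE)) abort("expression values must be nonnegative (FPKM)")
  rownames(m) <- expr$gene
  m
}

# rows of `m` for genes, erroring with the offending identifiers
gene_rows <- function(m, genes) {
  miss <- setdiff(unique(genes), rownames(m))
  if (length(miss) > 0) {
    abort(sprintf("gene(s) absent from expression matrix: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  m[genes, , drop = FALSE]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
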