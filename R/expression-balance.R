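#' Relative expression difference between two duplicate copies
#'
#' `rfpkm()` computes the normalized absolute expression difference
#' \eqn{R_{FPKM} = |E_1 - E_2| / (E_1 + E_2)} for a homeolog pair. The value
#' lies in \[0, 1\]: 0 means perfectly balanced expression, 1 means one copy
#' is completely silent. It is undefined (`NA`) when both copies are
#' unexpressed, since 0/0 carries no balance information.
#'
#' @param e1,e2 Nonnegative FPKM values (vectorized).
#' @return A numeric vector in \[0, 1\], `NA` where `e1 + e2 == 0`.
#' @examples
#' rfpkm(12.7, 0)   # one copy silenced -> 1
#' rfpkm(8.4, 8.4)  # balanced -> 0
#' @export
rfpkm <- function(e1, e2) {
  if (!is.numeric(e1) || !is.numeric(e2)) abort("FPKM values must be numeric")
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE)) {
    abort("FPKM values must be nonnegative")
  }
  s <- e1 + e2
  out <- abs(e1 - e2) / s
  out[s == 0] <- NA_real_
  out
}

#' Per-tissue R_FPKM for a table of homeolog pairs
#'
#' Applies [rfpkm()] column-wise over an expression matrix, returning one row
#' per pair and tissue. Tissues where both copies fall below `min_fpkm`
#' (default 0, i.e. only both-zero tissues) are marked `NA`.
#'
#' @param pairs A data frame with columns `copy1`, `copy2` (and optionally
#'   `pair_id`; one is derived if absent).
#' @param expr Expression tibble: a `gene` column plus one numeric FPKM
#'   column per tissue.
#' @param min_fpkm Optional floor; tissues with both copies strictly below it
#'   are treated as uninformative.
#' @return A tibble with columns `pair_id`, `copy1`, `copy2`, `tissue`,
#'   `rfpkm`.
#' @export
rfpkm_by_tissue <- function(pairs, expr, min_fpkm = 0) {
  pairs <- ensure_pair_id(pairs)
  m <- expression_matrix(expr)
  e1 <- gene_rows(m, pairs$copy1)
  e2 <- gene_rows(m, pairs$copy2)
  r <- rfpkm(e1, e2)
  r[e1 < min_fpkm & e2 < min_fpkm] <- NA_real_
  tibble::tibble(
    pair_id = rep(pairs$pair_id, times = ncol(m)),
    copy1   = rep(pairs$copy1, times = ncol(m)),
    copy2   = rep(pairs$copy2, times = ncol(m)),
    tissue  = rep(colnames(m), each = nrow(pairs)),
    rfpkm   = as.vector(r)
  )
}

#' Pair-level expression-balance profiles
#'
#' Summarises per-tissue R_FPKM into the per-pair average used throughout
#' the downstream analyses. The average is the arithmetic mean over
#' informative tissues only; pairs with no informative tissue are flagged
#' `informative = FALSE` and carry `NA` averages.
#'
#' @inheritParams rfpkm_by_tissue
#' @return A tibble with one row per pair: `pair_id`, `copy1`, `copy2`,
#'   `avg_rfpkm`, `n_informative_tissues`, `informative`.
#' @export
pair_balance <- function(pairs, expr, min_fpkm = 0) {
  pairs <- ensure_pair_id(pairs)
  m <- expression_matrix(expr)
  e1 <- gene_rows(m, pairs$copy1)
  e2 <- gene_rows(m, pairs$copy2)
  r <- rfpkm(e1, e2)
  r[e1 < min_fpkm & e2 < min_fpkm] <- NA_real_
  n_inf <- rowSums(!is.na(r))
  avg <- rowMeans(r, na.rm = TRUE)
  avg[n_inf == 0] <- NA_real_
  tibble::tibble(
    pair_id = pairs$pair_id, copy1 = pairs$copy1, copy2 = pairs$copy2,
    avg_rfpkm = unname(avg),
    n_informative_tissues = as.integer(unname(n_inf)),
    informative = unname(n_inf > 0)
  )
}

#' Tissue-specificity index tau for one expression profile
#'
#' \eqn{\tau = \sum_i (1 - x_i / x_{max}) / (N - 1)} with
#' \eqn{x_i = \log_2(\mathrm{FPKM}_i + 1)}. 0 indicates uniform expression
#' across tissues, 1 expression confined to a single tissue. Returns `NA`
#' for an all-zero profile.
#'
#' @param x Nonnegative FPKM vector over at least two tissues.
#' @return A scalar in \[0, 1\], or `NA` for an all-zero profile.
#' @examples
#' tissue_specificity_tau(c(3, 1, 0))  # 0.75
#' @export
tissue_specificity_tau <- function(x) {
  if (!is.numeric(x) || length(x) < 2) abort("tau needs a numeric vector over >= 2 tissues")
  if (any(x < 0, na.rm = TRUE)) abort("FPKM values must be nonnegative")
  if (all(x == 0)) return(NA_real_)
  lx <- log2(x + 1)
  sum(1 - lx / max(lx)) / (length(lx) - 1)
}

#' Tau for every gene of an expression matrix
#'
#' @inheritParams rfpkm_by_tissue
#' @return A tibble with columns `gene`, `tau` (`NA` for all-zero rows).
#' @export
expression_tau <- function(expr) {
  m <- expression_matrix(expr)
  if (ncol(m) < 2) abort("tau needs at least two tissues")
  tau <- apply(m, 1, function(x) if (all(x == 0)) NA_real_ else tissue_specificity_tau(x))
  tibble::tibble(gene = rownames(m), tau = unname(tau))
}

#' Consistency of expression balance across tissues
#'
#' Pearson correlation of per-tissue R_FPKM between every tissue pair,
#' computed on pairwise-complete pairs. Entries with fewer than three
#' complete observations are flagged not computable.
#'
#' @param rfpkm_long Output of [rfpkm_by_tissue()].
#' @return A tibble with columns `tissue_a`, `tissue_b`, `n`, `r`, `p`,
#'   `computable` for every unordered tissue pair.
#' @export
cross_tissue_consistency <- function(rfpkm_long) {
  check_columns(rfpkm_long, c("pair_id", "tissue", "rfpkm"), "rfpkm_long")
  wide <- tidyr::pivot_wider(
    rfpkm_long[c("pair_id", "tissue", "rfpkm")],
    names_from = "tissue", values_from = "rfpkm"
  )
  tissues <- setdiff(names(wide), "pair_id")
  combos <- utils::combn(tissues, 2, simplify = FALSE)
  purrr::map_dfr(combos, function(tt) {
    ok <- complete.cases(wide[[tt[1]]], wide[[tt[2]]])
    res <- pearson_test(wide[[tt[1]]][ok], wide[[tt[2]]][ok])
    dplyr::bind_cols(tibble::tibble(tissue_a = tt[1], tissue_b = tt[2]),
                     res[c("n", "r", "p", "computable")])
  })
}

#' Balance correlation of orthologous duplicate pairs across two species
#'
#' Tests whether orthologous homeolog pairs in two species show consistent
#' expression balance: a Pearson test on the average R_FPKM of linked pairs.
#'
#' @param profiles_a,profiles_b [pair_balance()] outputs for the two species.
#' @param ortholog_map Data frame with columns `pair_a`, `pair_b` linking
#'   `pair_id`s of `profiles_a` to `pair_id`s of `profiles_b`.
#' @return A one-row tibble: `n`, `r`, `p`, `computable`.
#' @export
cross_species_balance_correlation <- function(profiles_a, profiles_b, ortholog_map) {
  check_columns(ortholog_map, c("pair_a", "pair_b"), "ortholog_map")
  a <- profiles_a$avg_rfpkm[match(ortholog_map$pair_a, profiles_a$pair_id)]
  b <- profiles_b$avg_rfpkm[match(ortholog_map$pair_b, profiles_b$pair_id)]
  ok <- complete.cases(a, b)
  res <- pearson_test(a[ok], b[ok])
  res[c("n", "r", "p", "computable")]
}

#' Keep only the best anchor pair per tandem array
#'
#' When two or more syntenic anchor pairs involve the same tandem array,
#' only the pair with the lowest anchor e-value is retained; pairs without a
#' `tandem_array_id` pass through unchanged. Ties on the minimum e-value
#' keep the first pair in input order, so the filter is deterministic.
#'
#' @param pairs Pair table with optional columns `tandem_array_id`,
#'   `anchor_evalue`.
#' @return The filtered pair table, input order preserved.
#' @export
dedup_tandem_anchor_pairs <- function(pairs) {
  check_columns(pairs, c("copy1", "copy2"), "pairs")
  if (!"tandem_array_id" %in% names(pairs) || all(is.na(pairs$tandem_array_id))) {
    return(pairs)
  }
  grouped <- !is.na(pairs$tandem_array_id)
  if (!"anchor_evalue" %in% names(pairs)) {
    abort("pairs in tandem arrays need an anchor_evalue column")
  }
  bad <- unique(pairs$tandem_array_id[grouped & is.na(pairs$anchor_evalue)])
  if (length(bad) > 0) {
    abort(sprintf("tandem array group(s) with missing e-values: %s",
                  paste(bad, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(pairs))
  for (g in unique(pairs$tandem_array_id[grouped])) {
    idx <- which(grouped & pairs$tandem_array_id == g)
    best <- idx[which.min(pairs$anchor_evalue[idx])]  # which.min keeps first tie
    keep[setdiff(idx, best)] <- FALSE
  }
  pairs[keep, , drop = FALSE]
}
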