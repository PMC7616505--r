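#' Classify the higher- and lower-expressed copy of each pair per tissue
#'
#' Within each tissue, the copy with the higher FPKM is labelled the high
#' copy. Ties (including both copies at zero) carry no rank information and
#' are excluded.
#'
#' @param pairs Pair table.
#' @param expr Expression tibble (`gene` column plus tissue columns).
#' @param tissues Tissue labels to classify in; default all tissues.
#' @return A tibble: `pair_id`, `tissue`, `high_copy`, `low_copy`.
#' @export
classify_copies <- function(pairs, expr, tissues = NULL) {
  pairs <- ensure_pair_id(pairs)
  m <- expression_matrix(expr)
  tissues <- tissues %||% colnames(m)
  miss <- setdiff(tissues, colnames(m))
  if (length(miss) > 0) {
    abort(sprintf("tissue(s) absent from expression matrix: %s",
                  paste(miss, collapse = ", ")))
  }
  e1 <- gene_rows(m, pairs$copy1)[, tissues, drop = FALSE]
  e2 <- gene_rows(m, pairs$copy2)[, tissues, drop = FALSE]
  out <- tibble::tibble(
    pair_id = rep(pairs$pair_id, times = length(tissues)),
    tissue = rep(tissues, each = nrow(pairs)),
    copy1 = rep(pairs$copy1, times = length(tissues)),
    copy2 = rep(pairs$copy2, times = length(tissues)),
    v1 = as.vector(e1), v2 = as.vector(e2)
  )
  out <- out[out$v1 != out$v2, , drop = FALSE]
  tibble::tibble(
    pair_id = out$pair_id,
    tissue = out$tissue,
    high_copy = ifelse(out$v1 > out$v2, out$copy1, out$copy2),
    low_copy = ifelse(out$v1 > out$v2, out$copy2, out$copy1)
  )
}

#' Paired comparison of gene features between high and low copies
#'
#' For each requested feature, a two-sided paired t test on the per-pair
#' difference (high copy minus low copy). When assignments span several
#' tissues the test runs per tissue. Zero-variance difference vectors are
#' flagged not computable.
#'
#' @param assignments [classify_copies()] output.
#' @param features Per-gene feature tibble (a `gene` column plus feature
#'   columns; per-copy values are required, e.g. per-copy dN/dS estimates).
#' @param feature_names Character vector of feature columns to compare.
#' @return A tibble with one row per tissue and feature: `tissue`,
#'   `feature`, `n`, `mean_high`, `mean_low`, `t`, `df`, `p`, `computable`.
#' @export
paired_feature_comparison <- function(assignments, features,
                                      feature_names = intersect(ASSOC_FEATURES, names(features))) {
  check_columns(assignments, c("pair_id", "tissue", "high_copy", "low_copy"),
                "assignments")
  check_columns(features, "gene", "features")
  miss <- setdiff(feature_names, names(features))
  if (length(miss) > 0) {
    abort(sprintf("feature(s) absent from feature table: %s",
                  paste(miss, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(tissue = unique(assignments$tissue),
                             feature = feature_names)
  purrr::pmap_dfr(grid, function(tissue, feature) {
    a <- assignments[assignments$tissue == tissue, ]
    hi <- features[[feature]][match(a$high_copy, features$gene)]
    lo <- features[[feature]][match(a$low_copy, features$gene)]
    ok <- complete.cases(hi, lo)
    hi <- hi[ok]; lo <- lo[ok]
    n <- length(hi)
    base <- tibble::tibble(tissue = tissue, feature = feature, n = n,
                           mean_high = if (n) mean(hi) else NA_real_,
                           mean_low = if (n) mean(lo) else NA_real_)
    d <- hi - lo
    if (n < 2 || sd(d) == 0) {
      return(dplyr::mutate(base, t = NA_real_, df = NA_integer_,
                           p = NA_real_, computable = FALSE))
    }
    tt <- t.test(hi, lo, paired = TRUE)
    dplyr::mutate(base, t = unname(tt$statistic),
                  df = as.integer(tt$parameter),
                  p = tt$p.value, computable = TRUE)
  })
}

#' Premature-stop incidence in high versus low copies
#'
#' Each copy's fate label (high/low) is a per-copy property, while
#' classification is per tissue; the label is therefore resolved by
#' majority vote across the tissues where the pair is informative, with
#' exact ties excluded. The 2x2 table of fate class by stop status is then
#' tested with a Pearson chi-squared test.
#'
#' @param assignments [classify_copies()] output (any number of tissues).
#' @param stops Tibble with columns `gene`, `has_premature_stop`.
#' @param correct Apply the Yates continuity correction.
#' @return A one-row tibble: `high_stop`, `high_clean`, `low_stop`,
#'   `low_clean`, `chi2`, `df`, `p`, `computable`.
#' @export
stop_fate_comparison <- function(assignments, stops, correct = FALSE) {
  check_columns(assignments, c("pair_id", "high_copy", "low_copy"), "assignments")
  check_columns(stops, c("gene", "has_premature_stop"), "stops")
  votes <- dplyr::bind_rows(
    tibble::tibble(pair_id = assignments$pair_id,
                   gene = assignments$high_copy, vote = 1L),
    tibble::tibble(pair_id = assignments$pair_id,
                   gene = assignments$low_copy, vote = 0L)
  ) |>
    dplyr::group_by(.data$pair_id, .data$gene) |>
    dplyr::summarise(share_high = mean(.data$vote), .groups = "drop") |>
    dplyr::filter(.data$share_high != 0.5)
  if (nrow(votes) == 0) abort("no copies with a majority fate label")
  is_high <- votes$share_high > 0.5
  stop_flag <- stops$has_premature_stop[match(votes$gene, stops$gene)] > 0
  ok <- !is.na(stop_flag)
  # group FALSE -> first label; order chosen so counts read high then low
  chi2_2x2(!is_high[ok], stop_flag[ok], labels = c("high", "low"),
           correct = correct)
}
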