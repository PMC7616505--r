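#' Cis- and trans-regulatory divergence magnitudes
#'
#' From allele-specific expression components on the log scale — `A`, the
#' parental (between-species) expression difference, and `B`, the allelic
#' (cis) difference — the trans contribution is `A - B` by construction.
#' Adds the magnitudes `cis_mag = |B|`, `trans_mag = |A - B|` and
#' `total_mag = |B| + |A - B|` to the record table.
#'
#' @param ase Tibble with columns `gene`, `stage`, `A`, `B`.
#' @return `ase` with the three magnitude columns appended.
#' @export
regulatory_magnitudes <- function(ase) {
  check_columns(ase, c("A", "B"), "ase")
  if (any(!is.finite(ase$A)) || any(!is.finite(ase$B))) {
    abort("ASE components A and B must be finite")
  }
  dplyr::mutate(ase,
                cis_mag = abs(.data$B),
                trans_mag = abs(.data$A - .data$B),
                total_mag = abs(.data$B) + abs(.data$A - .data$B))
}

#' Association of regulatory-change magnitude with expression balance
#'
#' Tests whether homeolog pairs with larger relative expression differences
#' accumulate larger cis- and trans-regulatory changes. ASE records are
#' mapped to pairs through either copy, magnitudes are computed with
#' [regulatory_magnitudes()], and each magnitude (cis, trans, combined) is
#' regressed on the pair's average R_FPKM with AIC-selected linear/log
#' transform. By default each developmental stage is analysed separately.
#'
#' @param profiles [pair_balance()] output.
#' @param pairs Pair table.
#' @param ase ASE record tibble (`gene`, `stage`, `A`, `B`).
#' @param stages Optional stage labels to keep; default all.
#' @param pool_stages If `TRUE`, records from all retained stages are
#'   pooled into a single analysis.
#' @return A `homeolog_assoc` tibble with a `stage` column and one row per
#'   stage and component (`cis_mag`, `trans_mag`, `total_mag`).
#' @export
rfpkm_regulatory_association <- function(profiles, pairs, ase, stages = NULL,
                                         pool_stages = FALSE) {
  check_columns(ase, c("gene", "stage", "A", "B"), "ase")
  pairs <- ensure_pair_id(pairs)
  gene2pair <- tibble::tibble(
    gene = c(pairs$copy1, pairs$copy2),
    pair_id = rep(pairs$pair_id, 2)
  )
  df <- regulatory_magnitudes(ase) |>
    dplyr::inner_join(gene2pair, by = "gene")
  df$avg_rfpkm <- profiles$avg_rfpkm[match(df$pair_id, profiles$pair_id)]
  if (!is.null(stages)) df <- df[df$stage %in% stages, ]
  if (nrow(df) < 3) abort("fewer than 3 ASE records map to homeolog pairs")
  if (pool_stages) df$stage <- "pooled"
  out <- df |>
    dplyr::group_by(.data$stage) |>
    dplyr::group_modify(function(d, key) {
      dplyr::bind_rows(lapply(c("cis_mag", "trans_mag", "total_mag"), function(comp) {
        tidy(fit_linear_and_log(d[[comp]], d$avg_rfpkm, feature = comp))
      }))
    }) |>
    dplyr::ungroup()
  class(out) <- c("homeolog_assoc", class(out))
  out
}

#' Premature-stop-codon enrichment in expression-biased pairs
#'
#' Bins homeolog pairs by average R_FPKM at `threshold` (balanced:
#' `avg_rfpkm <= threshold`, biased: above it; the boundary belongs to the
#' balanced bin) and tests whether stop-bearing pairs are enriched among
#' biased pairs with a Pearson chi-squared test on the 2x2 table. A pair
#' counts as stop-bearing when either copy carries a premature stop
#' (`per_copy = TRUE` instead counts each copy separately).
#'
#' @param profiles [pair_balance()] output.
#' @param pairs Pair table.
#' @param stops Tibble with columns `gene`, `has_premature_stop` (0/1).
#' @param threshold Balance/bias cut on average R_FPKM.
#' @param per_copy Count copies instead of pairs.
#' @param correct Apply the Yates continuity correction (off by default).
#' @return A one-row tibble: bin-by-status counts (`balanced_stop`,
#'   `balanced_clean`, `biased_stop`, `biased_clean`), `chi2`, `df`, `p`,
#'   `computable`.
#' @export
stop_codon_bias <- function(profiles, pairs, stops, threshold = 0.6,
                            per_copy = FALSE, correct = FALSE) {
  check_columns(stops, c("gene", "has_premature_stop"), "stops")
  pairs <- ensure_pair_id(pairs)
  s1 <- stops$has_premature_stop[match(pairs$copy1, stops$gene)] > 0
  s2 <- stops$has_premature_stop[match(pairs$copy2, stops$gene)] > 0
  avg <- profiles$avg_rfpkm[match(pairs$pair_id, profiles$pair_id)]
  if (per_copy) {
    biased <- rep(avg > threshold, 2)
    stop_flag <- c(s1, s2)
  } else {
    biased <- avg > threshold
    stop_flag <- s1 | s2
  }
  ok <- !is.na(biased) & !is.na(stop_flag)
  chi2_2x2(biased[ok], stop_flag[ok],
           labels = c("balanced", "biased"), threshold = threshold,
           correct = correct)
}

# shared 2x2 chi-squared summary; `group` FALSE->labels[1], TRUE->labels[2]
chi2_2x2 <- function(group, flag, labels, threshold = NA_real_, correct = FALSE) {
  counts <- c(
    sum(!group & flag), sum(!group & !flag),
    sum(group & flag), sum(group & !flag)
  )
  out <- tibble::tibble(
    !!paste0(labels[1], "_stop") := counts[1],
    !!paste0(labels[1], "_clean") := counts[2],
    !!paste0(labels[2], "_stop") := counts[3],
    !!paste0(labels[2], "_clean") := counts[4]
  )
  if (!is.na(threshold)) out <- dplyr::mutate(out, threshold = threshold, .before = 1)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(dplyr::mutate(out, chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                         computable = FALSE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  dplyr::mutate(out, chi2 = unname(ct$statistic), df = as.integer(ct$parameter),
                p = unname(ct$p.value), computable = TRUE)
}
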