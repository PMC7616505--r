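# the fixed feature order of the association table
ASSOC_FEATURES <- c("dn", "ds", "omega", "exon_count", "cds_length",
                    "protein_length", "pfam_count", "tau", "ppi_count",
                    "lethal_score")

#' Pearson correlation test with Fisher-z confidence interval
#'
#' Standard Pearson r with \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, two-sided p from
#' the t distribution with n - 2 df, and a 95% CI from the Fisher z
#' transform (`NA` for n < 4, where the z standard error is undefined).
#' Inputs with fewer than three observations or zero variance are flagged
#' not computable rather than erroring, so callers can keep degenerate rows.
#'
#' @param x,y Equal-length numeric vectors; `NA`s must already be removed.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return A one-row tibble: `n`, `r`, `p`, `ci_low`, `ci_high`, `t`, `df`,
#'   `computable`.
#' @export
pearson_test <- function(x, y, conf_level = 0.95) {
  row1 <- function(...) {
    tibble::new_tibble(list(...), nrow = 1L)
  }
  not_comp <- row1(n = length(x), r = NA_real_, p = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_,
                   t = NA_real_, df = NA_integer_, computable = FALSE)
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 3 || anyNA(x) || anyNA(y)) return(not_comp)
  if (sd(x) == 0 || sd(y) == 0) return(not_comp)
  r <- cor(x, y)
  df <- n - 2L
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    crit <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * crit * se)
  } else {
    ci <- c(NA_real_, NA_real_)
    if (abs(r) >= 1) ci <- c(r, r)
  }
  row1(n = n, r = r, p = p, ci_low = ci[1], ci_high = ci[2],
       t = tstat, df = df, computable = TRUE)
}

# least-squares AIC on the scale used for model choice: n*ln(RSS/n) + 2k,
# k = 3 (intercept, slope, error variance). Only AIC differences matter.
ls_aic <- function(x, y) {
  n <- length(y)
  r <- cor(x, y)
  rss <- sum((y - mean(y))^2) * (1 - r^2)
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * 3
}

# offset rule for log transforms: plain log when all x > 0, log(x + 1)
# when zeros are present (keeps zero-count genes), no log when negative.
log_predictor <- function(x) {
  if (all(x > 0)) log(x) else if (all(x >= 0)) log1p(x) else NULL
}

#' Fit linear and log regressions of balance on a feature, choose by AIC
#'
#' Fits `y ~ x` and `y ~ log(x)` by least squares, compares them with the
#' least-squares AIC `n*ln(RSS/n) + 2k` (k = 3), and reports Pearson
#' statistics on the predictor of the lower-AIC model. Features containing
#' zeros use a `log(x + 1)` offset; features with negative values skip the
#' log model and report the linear fit.
#'
#' @param x Feature vector (predictor).
#' @param y Average R_FPKM vector (response).
#' @param feature Label carried into the result.
#' @return An object of class `rfpkm_assoc`; see [tidy.rfpkm_assoc()].
#' @export
fit_linear_and_log <- function(x, y, feature = "feature") {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  res <- list(feature = feature, n = n, transform = "linear",
              aic_linear = NA_real_, aic_log = NA_real_,
              test = pearson_test(numeric(0), numeric(0)))
  class(res) <- "rfpkm_assoc"
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    res$test$n <- n
    return(res)
  }
  res$aic_linear <- ls_aic(x, y)
  xl <- log_predictor(x)
  if (!is.null(xl) && sd(xl) > 0) res$aic_log <- ls_aic(xl, y)
  if (!is.na(res$aic_log) && res$aic_log < res$aic_linear) {
    res$transform <- "log"
    res$test <- pearson_test(xl, y)
  } else {
    res$test <- pearson_test(x, y)
  }
  res
}

#' @export
print.rfpkm_assoc <- function(x, ...) {
  cat(sprintf("<rfpkm_assoc> %s (%s): r = %.4f, p = %.3g, n = %d\n",
              x$feature, x$transform, x$test$r, x$test$p, x$n))
  invisible(x)
}

# pair-level feature values: arithmetic mean of the two copies
pair_features <- function(pairs, features,
                          feature_names = intersect(ASSOC_FEATURES, names(features))) {
  check_columns(features, "gene", "features")
  pairs <- ensure_pair_id(pairs)
  f1 <- features[match(pairs$copy1, features$gene), feature_names, drop = FALSE]
  f2 <- features[match(pairs$copy2, features$gene), feature_names, drop = FALSE]
  out <- tibble::tibble(pair_id = pairs$pair_id)
  for (fn in feature_names) out[[fn]] <- (f1[[fn]] + f2[[fn]]) / 2
  out
}

#' Association of average R_FPKM with gene features
#'
#' For each feature, forms the pair-level value as the mean of the two
#' copies' values, then fits linear and log regressions of average R_FPKM
#' on the feature and reports Pearson statistics for the AIC-chosen
#' transform. Rows are emitted in a fixed feature order (dN, dS, omega,
#' exon count, CDS length, protein length, Pfam count, tau, PPI count,
#' lethal score); features absent from the table or without variance are
#' flagged not computable rather than dropped.
#'
#' @param profiles [pair_balance()] output.
#' @param features Per-gene feature tibble with a `gene` column and any of
#'   the feature columns above.
#' @param pairs Pair table linking copies to pairs.
#' @param fdr If `TRUE`, append Benjamini-Hochberg adjusted p-values
#'   (`p_adj`). Off by default: the headline presentation uses raw p.
#' @return A tibble of class `homeolog_assoc`, one row per feature:
#'   `feature`, `transform`, `r`, `p`, `ci_low`, `ci_high`, `t`, `df`,
#'   `aic_linear`, `aic_log`, `n`, `computable`.
#' @export
feature_association_table <- function(profiles, features, pairs, fdr = FALSE) {
  check_columns(profiles, c("pair_id", "avg_rfpkm"), "profiles")
  pairs <- ensure_pair_id(pairs)
  have <- intersect(ASSOC_FEATURES, names(features))
  pf <- pair_features(pairs, features, have)
  y_all <- profiles$avg_rfpkm[match(pf$pair_id, profiles$pair_id)]
  rows <- purrr::map(ASSOC_FEATURES, function(fn) {
    if (!fn %in% have) {
      fit <- fit_linear_and_log(numeric(0), numeric(0), feature = fn)
    } else {
      fit <- fit_linear_and_log(pf[[fn]], y_all, feature = fn)
    }
    tidy(fit)
  })
  out <- dplyr::bind_rows(rows)
  if (fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("homeolog_assoc", class(out))
  out
}

#' Expression balance by GO-slim category
#'
#' A pair belongs to a category when either copy carries the label. Reports
#' the count, median and quartiles of average R_FPKM per category;
#' categories below `min_n` pairs are flagged.
#'
#' @param profiles [pair_balance()] output.
#' @param pairs Pair table.
#' @param go Long tibble with columns `gene`, `go_slim` (one row per
#'   gene-category assignment).
#' @param min_n Minimum pairs per category before the summary is trusted.
#' @return A tibble: `go_slim`, `n`, `median`, `q25`, `q75`, `below_min`.
#' @export
go_slim_summary <- function(profiles, pairs, go, min_n = 10) {
  check_columns(go, c("gene", "go_slim"), "go")
  pairs <- ensure_pair_id(pairs)
  if (nrow(go) == 0) {
    warning("empty GO map: returning empty summary")
    return(tibble::tibble(go_slim = character(), n = integer(),
                          median = numeric(), q25 = numeric(),
                          q75 = numeric(), below_min = logical()))
  }
  long <- dplyr::bind_rows(
    dplyr::inner_join(pairs[c("pair_id", "copy1")], go,
                      by = c(copy1 = "gene"))[c("pair_id", "go_slim")],
    dplyr::inner_join(pairs[c("pair_id", "copy2")], go,
                      by = c(copy2 = "gene"))[c("pair_id", "go_slim")]
  ) |> dplyr::distinct()
  long$avg_rfpkm <- profiles$avg_rfpkm[match(long$pair_id, profiles$pair_id)]
  long |>
    dplyr::filter(!is.na(.data$avg_rfpkm)) |>
    dplyr::group_by(.data$go_slim) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$avg_rfpkm),
      q25 = unname(quantile(.data$avg_rfpkm, 0.25)),
      q75 = unname(quantile(.data$avg_rfpkm, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::mutate(below_min = .data$n < min_n) |>
    dplyr::arrange(.data$median)
}

#' Robustness of feature associations to random pair deletion
#'
#' Emulates incomplete genome annotation by deleting a fraction of the
#' homeolog pairs at random (without replacement) and re-running the
#' Pearson test per feature on the retained subsample. The predictor
#' transform (linear or log) is fixed to the one chosen on the full data,
#' so replicates measure sampling stability, not model churn.
#'
#' @param profiles,features,pairs As in [feature_association_table()].
#' @param fractions Deletion fractions in \[0, 1).
#' @param replicates Resampling replicates per fraction.
#' @param seed Integer seed for the deletion draws.
#' @param alpha Significance threshold reported in `all_significant`.
#' @return A tibble with one row per feature and fraction: `feature`,
#'   `deletion_fraction`, `replicates`, `r_full`, `r_mean`, `r_sd`,
#'   `p_median`, `all_significant`.
#' @export
robustness_by_deletion <- function(profiles, features, pairs,
                                   fractions = c(0.025, 0.05, 0.10, 0.20, 0.40),
                                   replicates = 50, seed = 1, alpha = 0.05) {
  if (any(fractions < 0 | fractions >= 1)) abort("deletion fractions must lie in [0, 1)")
  if (replicates < 1) abort("replicates must be >= 1")
  pairs <- ensure_pair_id(pairs)
  have <- intersect(ASSOC_FEATURES, names(features))
  pf <- pair_features(pairs, features, have)
  y <- profiles$avg_rfpkm[match(pf$pair_id, profiles$pair_id)]
  full <- feature_association_table(profiles, features, pairs)
  set.seed(seed)
  grid <- tidyr::expand_grid(feature = have, deletion_fraction = sort(fractions))
  # one deletion draw set per fraction, shared across features, so the same
  # subsample underlies every feature's statistic (as in the real analysis)
  draws <- lapply(sort(unique(fractions)), function(f) {
    n_keep <- round(nrow(pf) * (1 - f))
    lapply(seq_len(replicates), function(i) sample.int(nrow(pf), n_keep))
  })
  names(draws) <- as.character(sort(unique(fractions)))
  purrr::pmap_dfr(grid, function(feature, deletion_fraction) {
    frow <- full[full$feature == feature, ]
    x_full <- pf[[feature]]
    if (frow$transform == "log") x_full <- log_predictor(x_full)
    stats <- purrr::map_dfr(draws[[as.character(deletion_fraction)]], function(idx) {
      ok <- complete.cases(x_full[idx], y[idx])
      pearson_test(x_full[idx][ok], y[idx][ok])[c("r", "p")]
    })
    tibble::tibble(
      feature = feature, deletion_fraction = deletion_fraction,
      replicates = replicates,
      r_full = frow$r, r_mean = mean(stats$r), r_sd = sd(stats$r),
      p_median = median(stats$p),
      all_significant = all(stats$p < alpha)
    )
  })
}
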