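test_that("pearson_test matches the brute-force covariance oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 5)
  o <- oracle_pearson(x, y)
  res <- pearson_test(x, y)
  expect_equal(res$r, o$r, tolerance = 1e-12)
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    o <- oracle_pearson(x, y)
    res <- pearson_test(x, y)
    expect_equal(res$r, o$r, tolerance = 1e-12)
    expect_equal(res$p, o$p, tolerance = 1e-12)
    expect_equal(res$ci_low, o$ci_low, tolerance = 1e-12)
    expect_equal(res$ci_high, o$ci_high, tolerance = 1e-12)
  }
})

test_that("pearson_test agrees with stats::cor.test", {
  set.seed(7)
  x <- rnorm(40); y <- 0.4 * x + rnorm(40)
  ct <- stats::cor.test(x, y)
  res <- pearson_test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$t, unname(ct$statistic), tolerance = 1e-12)
  expect_equal(c(res$ci_low, res$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-12)
})

test_that("pearson_test handles perfect and degenerate inputs", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$r, 1)
  expect_lt(pearson_test(x, 2 * x + 1)$p, 1e-12)
  expect_equal(pearson_test(x, -x)$r, -1)
  expect_false(pearson_test(x, rep(3, 10))$computable)
  expect_false(pearson_test(c(1, 2), c(3, 4))$computable)
})

test_that("Fisher-z CI contains r and narrows with n", {
  set.seed(11)
  widths <- sapply(c(10, 50, 200, 1000), function(n) {
    # fixed r = 0.5 by construction of the CI formula itself
    res <- pearson_test(seq_len(n), seq_len(n) + rnorm(n, 0, n / 4))
    expect_gte(res$r, res$ci_low)
    expect_lte(res$r, res$ci_high)
    res$ci_high - res$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("AIC selection recovers the generating transform", {
  set.seed(21)
  x <- runif(500, 0.5, 9)
  lin <- fit_linear_and_log(x, 0.2 + 0.05 * x, feature = "f")
  expect_equal(lin$transform, "linear")
  lg <- fit_linear_and_log(x, 0.3 * log(x), feature = "f")
  expect_equal(lg$transform, "log")
  noisy <- fit_linear_and_log(x, 0.3 * log(x) + rnorm(500, 0, 0.1))
  expect_lt(noisy$aic_log, noisy$aic_linear)
  # negative predictor values force the linear model
  x2 <- c(-1, runif(99))
  expect_equal(fit_linear_and_log(x2, rnorm(100))$transform, "linear")
})

test_that("AIC selection is invariant to adding a constant to the response", {
  set.seed(22)
  x <- runif(200, 0.1, 5); y <- 0.4 * log(x) + rnorm(200, 0, 0.2)
  f1 <- fit_linear_and_log(x, y)
  f2 <- fit_linear_and_log(x, y + 10)
  expect_equal(f1$transform, f2$transform)
  expect_equal(f1$aic_log - f1$aic_linear, f2$aic_log - f2$aic_linear,
               tolerance = 1e-9)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(23)
  fit <- fit_linear_and_log(runif(50, 1, 5), rnorm(50), feature = "dn")
  td <- tidy(fit)
  expect_named(td, c("feature", "transform", "r", "p", "ci_low", "ci_high",
                     "t", "df", "aic_linear", "aic_log", "n", "computable"))
  expect_equal(td$df, td$n - 2L)
  gl <- glance(fit)
  expect_equal(gl$delta_aic, gl$aic_log - gl$aic_linear)
})

test_that("the association table reproduces the expected sign pattern", {
  study <- small_study(seed = 2, n = 1200)
  prof <- pair_balance(study$pairs, study$expression)
  at <- feature_association_table(prof, study$features, study$pairs)
  expect_equal(at$feature, c("dn", "ds", "omega", "exon_count", "cds_length",
                             "protein_length", "pfam_count", "tau",
                             "ppi_count", "lethal_score"))
  neg <- c("exon_count", "cds_length", "protein_length", "pfam_count",
           "ppi_count", "lethal_score")
  pos <- c("dn", "ds", "tau")
  expect_true(all(at$r[at$feature %in% neg] < 0))
  expect_true(all(at$r[at$feature %in% pos] > 0))
  expect_true(all(at$p[at$feature %in% c(neg, pos)] < 0.01))
})

test_that("missing and constant features are flagged, not dropped", {
  study <- small_study(seed = 4, n = 100)
  prof <- pair_balance(study$pairs, study$expression)
  feats <- study$features[setdiff(names(study$features), "tau")]
  feats$ppi_count <- 3L
  at <- feature_association_table(prof, feats, study$pairs)
  expect_equal(nrow(at), 10)
  expect_false(at$computable[at$feature == "tau"])
  expect_false(at$computable[at$feature == "ppi_count"])
})

test_that("permuting features against profiles gives a null table", {
  study <- small_study(seed = 6, n = 1000)
  prof <- pair_balance(study$pairs, study$expression)
  set.seed(8)
  perm <- study$features
  idx <- sample(nrow(perm))
  perm[-1] <- perm[idx, -1]
  at <- feature_association_table(prof, perm, study$pairs)
  expect_true(all(abs(at$r) < 0.1))
})

test_that("GO-slim summaries split balanced from biased categories", {
  study <- small_study(seed = 9, n = 600)
  prof <- pair_balance(study$pairs, study$expression)
  # single category holding every pair reproduces the global median
  go_all <- tibble::tibble(gene = study$pairs$copy1, go_slim = "everything")
  gs <- go_slim_summary(prof, study$pairs, go_all)
  expect_equal(gs$median, median(prof$avg_rfpkm))
  # categories built from low-s vs high-s orthogroups order as expected
  s <- study$truth$s
  go2 <- dplyr::bind_rows(
    tibble::tibble(gene = study$pairs$copy1[s < 0.3], go_slim = "low_s"),
    tibble::tibble(gene = study$pairs$copy1[s > 0.7], go_slim = "high_s"))
  gs2 <- go_slim_summary(prof, study$pairs, go2)
  expect_gt(gs2$median[gs2$go_slim == "low_s"],
            gs2$median[gs2$go_slim == "high_s"])
  # a one-pair category is flagged below minimum
  go3 <- tibble::tibble(gene = study$pairs$copy1[1], go_slim = "lonely")
  expect_true(go_slim_summary(prof, study$pairs, go3)$below_min)
  expect_warning(go_slim_summary(prof, study$pairs, go3[0, ]), "empty")
})

test_that("deletion robustness is stable and seeded", {
  study <- small_study(seed = 10, n = 800)
  prof <- pair_balance(study$pairs, study$expression)
  rb <- robustness_by_deletion(prof, study$features, study$pairs,
                               fractions = c(0, 0.4), replicates = 10, seed = 2)
  # zero deletion reproduces the full-data correlation exactly
  z <- rb[rb$deletion_fraction == 0, ]
  expect_equal(z$r_mean, z$r_full, tolerance = 1e-12)
  expect_equal(z$r_sd, rep(0, nrow(z)), tolerance = 1e-12)
  # heavy deletion moves r only slightly for a strong feature
  d <- rb[rb$deletion_fraction == 0.4 & rb$feature == "dn", ]
  expect_lt(abs(d$r_mean - d$r_full), 0.05)
  rb2 <- robustness_by_deletion(prof, study$features, study$pairs,
                                fractions = c(0, 0.4), replicates = 10, seed = 2)
  expect_identical(rb, rb2)
  expect_error(robustness_by_deletion(prof, study$features, study$pairs,
                                      fractions = 1), "\\[0, 1\\)")
})
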