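test_that("rfpkm matches its definition on boundary and interior cases", {
  expect_equal(rfpkm(12.7, 0), 1)
  expect_equal(rfpkm(8.4, 8.4), 0)
  expect_equal(rfpkm(3, 1), 0.5)
  expect_true(is.na(rfpkm(0, 0)))
  expect_error(rfpkm(-1, 2), "nonnegative")
})

test_that("rfpkm is symmetric and scale-invariant", {
  set.seed(42)
  for (i in 1:200) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100); k <- runif(1, 0.01, 50)
    expect_identical(rfpkm(a, b), rfpkm(b, a))
    expect_equal(rfpkm(k * a, k * b), rfpkm(a, b), tolerance = 1e-12)
  }
})

test_that("pair balance averages over informative tissues only", {
  expr <- tibble::tibble(gene = c("x1", "x2"),
                         t1 = c(10, 10), t2 = c(0, 5), t3 = c(0, 0))
  pairs <- tibble::tibble(pair_id = "p", copy1 = "x1", copy2 = "x2")
  long <- rfpkm_by_tissue(pairs, expr)
  expect_equal(long$rfpkm, c(0, 1, NA))
  prof <- pair_balance(pairs, expr)
  expect_equal(prof$avg_rfpkm, 0.5)
  expect_equal(prof$n_informative_tissues, 2)
  expect_true(prof$informative)
})

test_that("a pair silent in every tissue is flagged non-informative", {
  prof <- pair_balance(tiny_pairs(), tiny_expr())
  pc <- prof[prof$pair_id == "pC", ]
  expect_false(pc$informative)
  expect_true(is.na(pc$avg_rfpkm))
  expect_equal(pc$n_informative_tissues, 0)
})

test_that("average balance lies within the range of per-tissue values", {
  study <- small_study(seed = 3, n = 150)
  long <- rfpkm_by_tissue(study$pairs, study$expression)
  prof <- pair_balance(study$pairs, study$expression)
  rng <- tapply(long$rfpkm, long$pair_id, range, na.rm = TRUE)
  for (p in prof$pair_id[prof$informative]) {
    expect_gte(prof$avg_rfpkm[prof$pair_id == p], rng[[p]][1])
    expect_lte(prof$avg_rfpkm[prof$pair_id == p], rng[[p]][2])
  }
})

test_that("missing genes are reported by name", {
  expect_error(
    pair_balance(tibble::tibble(copy1 = "nope", copy2 = "a1"), tiny_expr()),
    "nope")
})

test_that("tau matches hand-computed values and its boundary behaviour", {
  expect_equal(tissue_specificity_tau(c(3, 1, 0)), 0.75)
  expect_equal(tissue_specificity_tau(c(7, 7, 7, 7)), 0)
  expect_equal(tissue_specificity_tau(c(0, 9, 0)), 1)
  expect_true(is.na(tissue_specificity_tau(c(0, 0, 0))))
  tt <- expression_tau(tiny_expr())
  expect_equal(tt$tau[tt$gene == "c1"], NA_real_)
  expect_equal(nrow(tt), 6)
})

test_that("cross-tissue consistency recovers shared balance factors", {
  # duplicated tissue values give r = 1
  long <- tibble::tibble(pair_id = rep(c("p1", "p2", "p3"), 2),
                         tissue = rep(c("t1", "t2"), each = 3),
                         rfpkm = rep(c(0.1, 0.5, 0.9), 2))
  res <- cross_tissue_consistency(long)
  expect_equal(res$r, 1)
  # perfect affine relation between tissues
  long$rfpkm[4:6] <- c(0.2, 0.6, 1.0)
  expect_equal(cross_tissue_consistency(long)$r, 1)
  # synthetic study: shared per-pair factor makes all off-diagonals positive
  study <- small_study(seed = 5, n = 400)
  ct <- cross_tissue_consistency(rfpkm_by_tissue(study$pairs, study$expression))
  expect_true(all(ct$r > 0))
  expect_true(all(ct$p < 0.01))
})

test_that("cross-tissue entries with too few complete pairs are flagged", {
  long <- tibble::tibble(pair_id = c("p1", "p2", "p1", "p2"),
                         tissue = c("t1", "t1", "t2", "t2"),
                         rfpkm = c(0.1, 0.2, 0.3, 0.4))
  expect_false(cross_tissue_consistency(long)$computable)
})

test_that("cross-species balance correlation links orthologous pairs", {
  study <- small_study(seed = 7, n = 300)
  prof <- pair_balance(study$pairs, study$expression)
  idmap <- tibble::tibble(pair_a = prof$pair_id, pair_b = prof$pair_id)
  self <- cross_species_balance_correlation(prof, prof, idmap)
  expect_equal(self$r, 1)
  # two species sharing orthogroup sensitivity correlate positively
  study_b <- simulate_study(synthetic_config(n_orthogroups = 300, seed = 7,
                                             expression_noise_sd = 0.4))
  prof_b <- pair_balance(study_b$pairs, study_b$expression)
  res <- cross_species_balance_correlation(prof, prof_b, idmap)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.01)
  # a shuffled map destroys the association
  set.seed(1)
  shuf <- idmap
  shuf$pair_b <- sample(shuf$pair_b)
  expect_lt(abs(cross_species_balance_correlation(prof, prof_b, shuf)$r), 0.15)
})

test_that("tandem-array deduplication keeps the lowest e-value, stably", {
  pairs <- tibble::tibble(
    pair_id = c("p1", "p2", "p3", "p4"),
    copy1 = c("a", "b", "c", "d"), copy2 = c("a2", "b2", "c2", "d2"),
    anchor_evalue = c(1e-50, 1e-80, 1e-10, 1e-5),
    tandem_array_id = c("T1", "T1", "T1", NA))
  out <- dedup_tandem_anchor_pairs(pairs)
  expect_equal(out$pair_id, c("p2", "p4"))
  # no annotations: identity
  plain <- tiny_pairs()
  expect_identical(dedup_tandem_anchor_pairs(plain), plain)
  # ties keep the first in input order, under either ordering
  tied <- pairs
  tied$anchor_evalue <- c(1e-80, 1e-80, 1e-10, 1e-5)
  expect_equal(dedup_tandem_anchor_pairs(tied)$pair_id, c("p1", "p4"))
  rev_tied <- tied[c(2, 1, 3, 4), ]
  expect_equal(dedup_tandem_anchor_pairs(rev_tied)$pair_id, c("p2", "p4"))
  # missing e-values inside a group are an error naming the group
  bad <- pairs
  bad$anchor_evalue[1] <- NA
  expect_error(dedup_tandem_anchor_pairs(bad), "T1")
})
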