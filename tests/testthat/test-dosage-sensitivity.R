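test_that("expected copy numbers are products of event multipliers", {
  expect_equal(expected_copy_number(integer(0)), 1L)
  expect_equal(expected_copy_number(3), 3L)
  expect_equal(expected_copy_number(c(3, 2, 2, 3)), 36L)
  expect_equal(expected_copy_number(c(2, 3, 3, 2)), 36L)  # order-invariant
  expect_error(expected_copy_number(c(1, 2)), ">= 2")
  tbl <- expected_copies_from_histories(
    tibble::tibble(species = c("amb", "vit", "bra"),
                   events = list(integer(0), 3L, c(3L, 2L, 2L, 3L))))
  expect_equal(tbl$expected, c(1L, 3L, 36L))
  # string encodings parse identically
  tbl2 <- expected_copies_from_histories(
    tibble::tibble(species = c("amb", "vit", "bra"),
                   events = c(".", "3", "3,2,2,3")))
  expect_equal(tbl2$expected, tbl$expected)
})

test_that("r_copy_number is 1 for affine-matching profiles and flags degeneracy", {
  e <- c(1, 3, 36, 2, 4, 12, 6)
  expect_equal(r_copy_number(e, e)$r, 1)
  expect_equal(r_copy_number(2 * e + 1, e)$r, 1)
  expect_false(r_copy_number(rep(1, 7), e)$computable)
  expect_false(r_copy_number(e, rep(2, 7))$computable)
  # named vectors align by species
  obs <- setNames(c(36, 1, 3), c("bra", "amb", "vit"))
  exp <- setNames(c(1, 3, 36), c("amb", "vit", "bra"))
  expect_equal(r_copy_number(obs, exp)$r, 1)
})

test_that("copy simulation honours its boundary contracts", {
  hist <- default_wgd_panel()
  # s = 1: no loss possible, observed equals expected exactly
  set.seed(1)
  out <- simulate_orthogroup_copies(1, hist, loss_rate_base = 0.9)
  expect_equal(out$observed, out$expected)
  # certain loss: every lineage with an event history ends at zero
  set.seed(2)
  out0 <- simulate_orthogroup_copies(0, hist, loss_rate_base = 1)
  has_events <- lengths(homeobalance:::parse_events(hist$events)) > 0
  expect_true(all(out0$observed[has_events] == 0))
  expect_true(all(out0$observed[!has_events] == 1))
  expect_error(simulate_orthogroup_copies(1.5, hist), "\\[0, 1\\]")
})

test_that("mean observed/expected ratio matches the analytic survival product", {
  hist <- default_wgd_panel()
  s <- 0.5; base <- 0.4
  q <- base * (1 - s)
  k <- lengths(homeobalance:::parse_events(hist$events))
  surv <- (1 - q)^k  # per-lineage closed form
  set.seed(33)
  reps <- t(sapply(1:500, function(i) {
    simulate_orthogroup_copies(s, hist, base)$observed
  }))
  expected <- expected_copies_from_histories(hist)$expected
  ratio <- colMeans(reps) / expected
  se <- apply(t(t(reps) / expected), 2, sd) / sqrt(500)
  expect_true(all(abs(ratio - surv) <= 3 * pmax(se, 1e-12)))
})

test_that("pgl matches hand-derived values on the quartet tree", {
  tr <- quartet_tree()
  expect_equal(pgl(setNames(c(1, 1, 1, 1), c("A", "B", "C", "D")), tr), 0)
  # one tip absent: one terminal loss branch out of 6 units
  expect_equal(pgl(setNames(c(1, 1, 1, 0), c("A", "B", "C", "D")), tr), 1 / 6)
  # an absent sister cherry lies outside the gain clade: no loss inferred
  expect_equal(pgl(setNames(c(1, 1, 0, 0), c("A", "B", "C", "D")), tr), 0)
  # gain node restricted to the carrying cherry: no losses inside it
  expect_equal(pgl(setNames(c(1, 0, 0, 0), c("A", "B", "C", "D")), tr), 0)
  # a cherry nested inside the gain clade is lost via its stem, not two tips
  tr5 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  expect_equal(pgl(setNames(c(1, 1, 0, 0, 1), c("A", "B", "C", "D", "E")), tr5),
               1 / 8)
  expect_error(pgl(setNames(c(0, 0, 0, 0), c("A", "B", "C", "D")), tr),
               "absent in all")
})

test_that("pgl equals the exhaustive Dollo oracle on small random trees", {
  set.seed(55)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tr <- random_tree(n)
    pres <- setNames(rbinom(n, 1, 0.6), tr$tip.label)
    if (sum(pres) == 0) pres[sample(n, 1)] <- 1
    expect_equal(pgl(pres, tr), oracle_pgl(pres, tr), tolerance = 1e-12)
  }
})

test_that("pgl is invariant to rescaling branch lengths", {
  set.seed(56)
  tr <- random_tree(6)
  pres <- setNames(c(1, 0, 1, 1, 0, 1), tr$tip.label)
  v1 <- pgl(pres, tr)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  expect_equal(pgl(pres, tr2), v1, tolerance = 1e-12)
})

test_that("orthogroup dosage profiles separate sensitive from insensitive groups", {
  hist <- default_wgd_panel()
  set.seed(77)
  r_hi <- replicate(150, {
    r_copy_number(simulate_orthogroup_copies(0.9, hist, 0.4)$observed,
                  expected_copies_from_histories(hist)$expected)$r
  })
  r_lo <- replicate(150, {
    r_copy_number(simulate_orthogroup_copies(0.1, hist, 0.4)$observed,
                  expected_copies_from_histories(hist)$expected)$r
  })
  expect_gt(mean(r_hi), mean(r_lo))
})

test_that("balance associates negatively with dosage sensitivity, positively with loss", {
  study <- small_study(seed = 12, n = 1200)
  prof <- pair_balance(study$pairs, study$expression)
  ogp <- og_dosage_profiles(study$copy_numbers, study$histories, study$tree)
  expect_equal(nrow(ogp), 1200)
  da <- dosage_balance_association(prof, study$og_map, ogp)
  expect_lt(da$r[da$feature == "r_copy_number"], 0)
  expect_gt(da$r[da$feature == "pgl"], 0)
  expect_true(all(da$p < 0.01))
  # shuffling the orthogroup map destroys the association
  set.seed(13)
  shuf <- study$og_map
  shuf$og_id <- sample(shuf$og_id)
  da2 <- dosage_balance_association(prof, shuf, ogp)
  expect_true(all(abs(da2$r) < 0.1))
})

test_that("og_dosage_profiles agrees with the scalar pgl and r_copy_number", {
  study <- small_study(seed = 14, n = 40)
  ogp <- og_dosage_profiles(study$copy_numbers, study$histories, study$tree)
  expected <- expected_copies_from_histories(study$histories)
  species <- study$histories$species
  for (i in c(1, 7, 25)) {
    obs <- as.numeric(study$copy_numbers[i, species])
    ref <- r_copy_number(setNames(obs, species),
                         setNames(expected$expected, expected$species))
    expect_equal(ogp$r_copy_number[i], ref$r, tolerance = 1e-12)
    if (any(obs > 0)) {
      expect_equal(ogp$pgl[i], pgl(setNames(obs > 0, species), study$tree),
                   tolerance = 1e-12)
    }
  }
})
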