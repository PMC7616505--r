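#' Expected copy number after a lineage's polyploidy history
#'
#' The expected number of surviving descendants of one ancestral gene copy
#' is the product of the lineage's whole-genome multiplication factors
#' (2 for a WGD, 3 for a WGT): a lineage with a gamma-like triplication
#' expects 3 copies, one with events 3, 2, 2, 3 expects 36. A lineage with
#' no events expects 1.
#'
#' @param events Integer vector of event multipliers (each >= 2), oldest
#'   first; order does not affect the product.
#' @return A positive integer.
#' @examples
#' expected_copy_number(integer(0))   # 1
#' expected_copy_number(c(3))         # 3
#' expected_copy_number(c(3, 2, 2, 3))# 36
#' @export
expected_copy_number <- function(events) {
  if (length(events) == 0) return(1L)
  if (!is.numeric(events) || any(events != round(events)) || any(events < 2)) {
    abort("event multipliers must be integers >= 2")
  }
  as.integer(prod(events))
}

#' Expected copy numbers for a panel of lineages
#'
#' @param histories Tibble with columns `species` and `events`, where
#'   `events` is a list-column of integer multipliers (or a comma-separated
#'   string such as `"3,2,2,3"`; `"."` or `""` meaning no events).
#' @return A tibble: `species`, `expected`.
#' @export
expected_copies_from_histories <- function(histories) {
  check_columns(histories, c("species", "events"), "histories")
  ev <- parse_events(histories$events)
  tibble::tibble(
    species = histories$species,
    expected = vapply(ev, expected_copy_number, integer(1))
  )
}

# accept list-column of integer vectors or "3,2,2" strings
parse_events <- function(events) {
  if (is.list(events)) {
    return(lapply(events, function(e) if (is.null(e)) integer(0) else as.integer(e)))
  }
  lapply(as.character(events), function(s) {
    if (is.na(s) || s %in% c("", ".")) return(integer(0))
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Observed-vs-expected copy-number correlation for one orthogroup
#'
#' The per-orthogroup dosage-sensitivity proxy: a Pearson test between the
#' observed copy number per species and the copy number expected from each
#' lineage's polyploidy history. High values indicate that copy number
#' tracks the number of genome multiplications, the signature of a
#' dosage-sensitive gene family.
#'
#' @param observed,expected Numeric vectors over the same species (matched
#'   by name when both are named).
#' @return A one-row tibble: `n`, `r`, `p`, `computable` (`FALSE` when
#'   either vector has zero variance or fewer than three species).
#' @export
r_copy_number <- function(observed, expected) {
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    common <- intersect(names(observed), names(expected))
    observed <- observed[common]
    expected <- expected[common]
  }
  ok <- complete.cases(observed, expected)
  pearson_test(as.numeric(observed[ok]), as.numeric(expected[ok]))[
    c("n", "r", "p", "computable")]
}

# ---- Dollo-parsimony propensity for gene loss ------------------------------

# precompute reusable tree structure: postorder edges, per-node tip lists
pgl_tree_cache <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree must carry branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # descendant-tip indicator: desc[node, tip] via postorder accumulation
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  # node containment: contain[a, d] TRUE iff node d lies in the clade of a
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  contain <- diag(nnode) > 0
  for (d in seq_len(nnode)) {
    a <- d
    while (a != root) {
      a <- parent[a]
      contain[a, d] <- TRUE
    }
  }
  list(tree = tree, ntip = ntip, nnode = nnode,
       edge = tree$edge, edge_length = tree$edge.length,
       desc = desc, clade_size = rowSums(desc), contain = contain)
}

# vectorized Dollo PGL over a presence matrix (orthogroups x species)
pgl_matrix <- function(P, cache) {
  tips <- cache$tree$tip.label
  miss <- setdiff(tips, colnames(P))
  if (length(miss) > 0) {
    abort(sprintf("presence matrix lacks tree tip(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  P <- P[, tips, drop = FALSE] > 0
  n_og <- nrow(P)
  if (any(rowSums(P) == 0)) abort("orthogroup absent in all species has no gain node")
  # count of present tips below every node, per orthogroup
  cnt <- matrix(0L, cache$nnode, n_og)
  cnt[seq_len(cache$ntip), ] <- t(P) * 1L
  for (e in seq_len(nrow(cache$edge))) {
    p <- cache$edge[e, 1]; ch <- cache$edge[e, 2]
    cnt[p, ] <- cnt[p, ] + cnt[ch, ]
  }
  total <- rowSums(P)
  # gain node: smallest clade containing all present tips (the MRCA)
  score <- matrix(cache$clade_size, cache$nnode, n_og)
  score[cnt != rep(total, each = cache$nnode)] <- Inf
  mrca <- apply(score, 2, which.min)
  # edge (p, ch) is inside the gain clade iff p descends from (or is) mrca;
  # it is a loss edge iff additionally no present tip lies below ch
  parent_in <- matrix(FALSE, nrow(cache$edge), n_og)
  for (e in seq_len(nrow(cache$edge))) {
    p <- cache$edge[e, 1]
    parent_in[e, ] <- cache$contain[cbind(mrca, p)]
  }
  child_cnt <- cnt[cache$edge[, 2], , drop = FALSE]
  parent_cnt <- cnt[cache$edge[, 1], , drop = FALSE]
  loss <- parent_in & child_cnt == 0 & parent_cnt > 0
  len <- cache$edge_length
  loss_len <- colSums(loss * len)
  total_len <- colSums(parent_in * len)
  out <- ifelse(total_len > 0, loss_len / total_len, 0)
  unname(out)
}

#' Dollo-parsimony propensity for gene loss
#'
#' Places a single gain at the most recent common ancestor of the species
#' carrying the gene and infers losses parsimoniously: a branch is a loss
#' branch when its parent clade still contains a carrier but no species
#' below the branch does. This minimal placement (losses as few and as deep
#' as possible) is unique under Dollo parsimony. PGL is the summed length
#' of loss branches divided by the total branch length of the clade
#' descending from the gain node; 0 when no losses occurred (including the
#' degenerate single-carrier case, which offers no loss opportunity).
#'
#' @param presence Named 0/1 (or logical) vector over the tree's tips.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return A nonnegative scalar.
#' @export
pgl <- function(presence, tree) {
  if (is.null(names(presence))) abort("presence must be named by species")
  cache <- pgl_tree_cache(tree)
  P <- matrix(as.numeric(presence), nrow = 1,
              dimnames = list(NULL, names(presence)))
  pgl_matrix(P, cache)
}

#' Orthogroup dosage profiles from a copy-number matrix
#'
#' Computes, per orthogroup, the observed-vs-expected copy-number
#' correlation and the Dollo-parsimony propensity for gene loss.
#'
#' @param copy_numbers Tibble with an `og_id` column and one integer column
#'   per species.
#' @param histories Lineage polyploidy histories
#'   (see [expected_copies_from_histories()]).
#' @param tree Rooted species tree (`phylo`) covering all species columns.
#' @return A tibble: `og_id`, `n_species`, `r_copy_number`, `r_p`,
#'   `computable`, `pgl`.
#' @export
og_dosage_profiles <- function(copy_numbers, histories, tree) {
  check_columns(copy_numbers, "og_id", "copy_numbers")
  species <- setdiff(names(copy_numbers), "og_id")
  exp_tbl <- expected_copies_from_histories(histories)
  miss <- setdiff(species, exp_tbl$species)
  if (length(miss) > 0) {
    abort(sprintf("species without a polyploidy history: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  e <- exp_tbl$expected[match(species, exp_tbl$species)]
  O <- as.matrix(copy_numbers[species])
  # vectorized Pearson of every row against the shared expected vector
  ec <- e - mean(e)
  oc <- O - rowMeans(O)
  denom <- sqrt(rowSums(oc^2)) * sqrt(sum(ec^2))
  r <- as.vector(oc %*% ec) / denom
  n <- length(e)
  df <- n - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  computable <- is.finite(r) & denom > 0 & n >= 3
  r[!computable] <- NA_real_
  p[!computable] <- NA_real_
  pres <- O > 0
  colnames(pres) <- species
  cache <- pgl_tree_cache(tree)
  pgl_vals <- rep(NA_real_, nrow(O))
  has_any <- rowSums(pres) > 0
  if (any(has_any)) pgl_vals[has_any] <- pgl_matrix(pres[has_any, , drop = FALSE], cache)
  tibble::tibble(
    og_id = copy_numbers$og_id,
    n_species = n,
    r_copy_number = r,
    r_p = p,
    computable = computable,
    pgl = pgl_vals
  )
}

#' Association of expression balance with dosage-sensitivity scores
#'
#' Two AIC-selected associations of average R_FPKM: against the
#' observed-vs-expected copy-number correlation and against the propensity
#' for gene loss. Under dosage-balance constraint the first is negative
#' (balanced pairs belong to dosage-sensitive orthogroups) and the second
#' positive (diverged pairs belong to loss-prone orthogroups).
#'
#' @param profiles [pair_balance()] output.
#' @param og_map Tibble with columns `pair_id`, `og_id` mapping pairs to
#'   orthogroups.
#' @param og_profiles [og_dosage_profiles()] output.
#' @return A `homeolog_assoc` tibble with rows `r_copy_number` and `pgl`.
#' @export
dosage_balance_association <- function(profiles, og_map, og_profiles) {
  check_columns(og_map, c("pair_id", "og_id"), "og_map")
  if (nrow(og_map) == 0) abort("empty pair-to-orthogroup mapping")
  y <- profiles$avg_rfpkm[match(og_map$pair_id, profiles$pair_id)]
  idx <- match(og_map$og_id, og_profiles$og_id)
  rcn <- og_profiles$r_copy_number[idx]
  pglv <- og_profiles$pgl[idx]
  out <- dplyr::bind_rows(
    tidy(fit_linear_and_log(rcn, y, feature = "r_copy_number")),
    tidy(fit_linear_and_log(pglv, y, feature = "pgl"))
  )
  class(out) <- c("homeolog_assoc", class(out))
  out
}
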