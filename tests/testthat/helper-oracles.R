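# independent brute-force oracles, kept deliberately naive

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  z <- 0.5 * log((1 + r) / (1 - r))
  se <- 1 / sqrt(n - 3)
  ci <- (function(zz) (exp(2 * zz) - 1) / (exp(2 * zz) + 1))(
    z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, t = t, p = p, ci_low = ci[1], ci_high = ci[2])
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(chi2 = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# exhaustive Dollo oracle: enumerate every subset of edges inside the gain
# clade as candidate loss placements, keep those reproducing the absence
# pattern, take the minimum-cardinality one (unique for Dollo)
oracle_pgl <- function(presence, tree) {
  pres <- as.logical(presence[tree$tip.label])
  ntip <- length(tree$tip.label)
  stopifnot(any(pres))
  # tips below each node
  below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  nnode <- ntip + tree$Nnode
  tips_below <- lapply(seq_len(nnode), below)
  present_tips <- which(pres)
  # gain node: smallest clade containing all present tips
  cands <- which(vapply(tips_below, function(tb) all(present_tips %in% tb), TRUE))
  gain <- cands[which.min(lengths(tips_below[cands]))]
  # all nodes inside the gain clade (edges whose parent lies in it)
  clade_nodes <- gain
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% clade_nodes, 2]
    nxt <- union(clade_nodes, kids)
    if (length(nxt) == length(clade_nodes)) break
    clade_nodes <- nxt
  }
  edges <- which(tree$edge[, 1] %in% clade_nodes)
  total_len <- sum(tree$edge.length[edges])
  if (total_len == 0 || length(edges) == 0) return(0)
  clade_tips <- intersect(clade_nodes, seq_len(ntip))
  best_k <- Inf; best_len <- NULL
  for (mask in 0:(2^length(edges) - 1)) {
    sel <- edges[bitwAnd(mask, 2^(seq_along(edges) - 1)) > 0]
    if (length(sel) >= best_k) next
    # a clade tip ends up absent iff a selected edge lies on its path
    lost <- rep(FALSE, ntip)
    for (e in sel) lost[intersect(tips_below[[tree$edge[e, 2]]], seq_len(ntip))] <- TRUE
    if (all(lost[clade_tips] == !pres[clade_tips])) {
      best_k <- length(sel)
      best_len <- sum(tree$edge.length[sel])
    }
  }
  stopifnot(is.finite(best_k))
  best_len / total_len
}

random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- round(runif(nrow(tr$edge), 0.1, 2), 3)
  tr
}
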