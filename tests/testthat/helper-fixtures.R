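# small fixtures shared across tests, built in code

tiny_expr <- function() {
  tibble::tibble(
    gene = c("a1", "a2", "b1", "b2", "c1", "c2"),
    root   = c(10,  10,   0,   5,   0,   0),
    leaf   = c(3,    1,   2,   2,   0,   0),
    flower = c(0,    4,   8,   0,   0,   0)
  )
}

tiny_pairs <- function() {
  tibble::tibble(pair_id = c("pA", "pB", "pC"),
                 copy1 = c("a1", "b1", "c1"),
                 copy2 = c("a2", "b2", "c2"))
}

# 4-tip symmetric tree with unit branch lengths
quartet_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

small_study <- function(seed = 1, n = 300, ...) {
  simulate_study(synthetic_config(n_orthogroups = n, seed = seed, ...))
}
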