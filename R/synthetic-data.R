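# fixed 25-lineage panel and species tree used by the default synthetic study

DEFAULT_TREE_NEWICK <- "((sp17:0.831,(((sp05:0.417,sp21:0.172):0.113,(sp12:0.853,sp22:0.108):0.787):0.936,(sp25:0.566,sp23:0.194):0.741):0.246):0.94,((((((((sp04:0.267,((sp02:0.75,sp13:0.689):0.805,sp08:0.219):0.749):0.755,sp14:0.79):0.408,sp11:0.934):0.413,(sp24:0.691,sp16:0.766):0.943):0.843,sp09:0.967):0.517,(sp10:0.738,sp06:0.294):0.834):0.984,(sp01:0.43,(sp19:0.197,sp18:0.457):0.543):0.401):0.565,(sp20:0.038,((sp07:0.517,sp15:0.972):0.312,sp03:0.81):0.962):0.793):0.117);"

#' Default 25-lineage polyploidy panel
#'
#' A fixed panel of 25 lineages whose event histories span the realistic
#' range for angiosperms: from no lineage-specific polyploidy (expected
#' copy number 1), through a single triplication (3), up to a
#' triplication-two-duplications-triplication history (36).
#'
#' @return A tibble with columns `species` and `events` (list-column of
#'   integer multipliers, oldest first).
#' @export
default_wgd_panel <- function() {
  ev <- list(
    sp01 = integer(0), sp02 = integer(0), sp03 = 2L, sp04 = 2L, sp05 = 3L,
    sp06 = 2L, sp07 = c(2L, 2L), sp08 = c(2L, 2L), sp09 = c(3L, 2L),
    sp10 = c(2L, 3L), sp11 = c(2L, 2L, 2L), sp12 = c(3L, 2L, 2L),
    sp13 = c(3L, 2L, 2L, 3L), sp14 = 2L, sp15 = c(2L, 2L), sp16 = 3L,
    sp17 = c(2L, 2L, 2L), sp18 = c(2L, 3L), sp19 = 2L, sp20 = c(2L, 2L),
    sp21 = c(3L, 2L), sp22 = 2L, sp23 = c(2L, 2L, 3L), sp24 = c(2L, 2L),
    sp25 = c(3L, 3L)
  )
  tibble::tibble(species = names(ev), events = unname(ev))
}

#' Default species tree for the synthetic panel
#'
#' @return A rooted 25-tip `phylo` tree with branch lengths, tips matching
#'   [default_wgd_panel()].
#' @export
default_species_tree <- function() {
  ape::read.tree(text = DEFAULT_TREE_NEWICK)
}

#' Configuration of a synthetic homeolog study
#'
#' Bundles and validates the parameters of the generator. A latent
#' dosage-sensitivity parameter `s` in \[0, 1\] per orthogroup (Beta
#' distributed) jointly drives expression balance, copy retention across
#' the species panel, sequence divergence, regulatory-change magnitude and
#' premature-stop incidence; `effect_sizes` holds the slopes of each
#' coupling, so setting them all to zero yields a null study.
#'
#' @param n_orthogroups Number of orthogroups (one focal homeolog pair each).
#' @param n_tissues Number of tissues in the expression matrix.
#' @param n_stages Developmental stages for ASE records.
#' @param wgd_histories Lineage polyploidy histories (tibble `species`,
#'   `events`); defaults to [default_wgd_panel()].
#' @param tree Species tree (`phylo`) over the panel.
#' @param sensitivity_shape1,sensitivity_shape2 Beta shape parameters of
#'   the latent sensitivity `s`.
#' @param s_fixed Optional fixed value for `s` (overrides the Beta draw;
#'   used for degenerate checks).
#' @param loss_rate_base Per-branch loss probability at `s = 0`; the loss
#'   probability used anywhere is `loss_rate_base * (1 - s)`.
#' @param expression_noise_sd Log-scale sd of per-copy expression noise.
#' @param effect_sizes Named list of coupling slopes: `balance` (copy-2
#'   downscaling exponent per unit `(1 - s)`), `dn`/`ds` (log-scale slope
#'   of substitution rates on realized average R_FPKM), `protein_length`,
#'   `exon`, `pfam`, `ppi` (log-scale slopes on `s`), `lethal` (logit
#'   slope on `s`), `tau` (slope of tissue specificity on `1 - s`), `stop`
#'   (logit slope of premature-stop probability on average R_FPKM), `ase`
#'   (scale of cis/trans magnitudes), `fate` (per-copy divergence asymmetry
#'   disfavouring the lower-expressed copy).
#' @param seed Integer master seed; every sub-generator draws from its own
#'   stream split off this seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_orthogroups = 2000,
                             n_tissues = 10,
                             n_stages = 2,
                             wgd_histories = default_wgd_panel(),
                             tree = default_species_tree(),
                             sensitivity_shape1 = 2,
                             sensitivity_shape2 = 2,
                             s_fixed = NULL,
                             loss_rate_base = 0.4,
                             expression_noise_sd = 0.25,
                             effect_sizes = default_effect_sizes(),
                             seed = 1) {
  cfg <- list(n_orthogroups = n_orthogroups, n_tissues = n_tissues,
              n_stages = n_stages, wgd_histories = wgd_histories, tree = tree,
              sensitivity_shape1 = sensitivity_shape1,
              sensitivity_shape2 = sensitivity_shape2, s_fixed = s_fixed,
              loss_rate_base = loss_rate_base,
              expression_noise_sd = expression_noise_sd,
              effect_sizes = utils::modifyList(default_effect_sizes(), effect_sizes),
              seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Default coupling slopes of the synthetic study
#'
#' @return A named list of effect sizes; see [synthetic_config()].
#' @export
default_effect_sizes <- function() {
  list(balance = 2, dn = 0.8, ds = 0.7, protein_length = 0.5, exon = 1.0,
       pfam = 0.8, ppi = 0.7, lethal = 0.9, tau = 0.35, stop = 2.2,
       ase = 1, fate = 0.5)
}

validate_synthetic_config <- function(cfg) {
  for (fld in c("n_orthogroups", "n_tissues", "n_stages")) {
    v <- cfg[[fld]]
    if (!is_scalar_number(v) || v < 1 || v != round(v)) {
      abort(sprintf("invalid config: %s must be a positive integer", fld))
    }
  }
  check_columns(cfg$wgd_histories, c("species", "events"), "wgd_histories")
  mults <- unlist(parse_events(cfg$wgd_histories$events))
  if (length(mults) > 0 && any(!mults %in% c(2L, 3L))) {
    abort("invalid config: wgd_histories event multipliers must be 2 or 3")
  }
  if (!inherits(cfg$tree, "phylo")) abort("invalid config: tree must be a phylo object")
  miss <- setdiff(cfg$wgd_histories$species, cfg$tree$tip.label)
  if (length(miss) > 0) {
    abort(sprintf("invalid config: species missing from tree: %s",
                  paste(head(miss, 5), collapse = ", ")))
  }
  for (fld in c("sensitivity_shape1", "sensitivity_shape2")) {
    if (!is_scalar_number(cfg[[fld]]) || cfg[[fld]] <= 0) {
      abort(sprintf("invalid config: %s must be positive", fld))
    }
  }
  if (!is.null(cfg$s_fixed) &&
      (!is_scalar_number(cfg$s_fixed) || cfg$s_fixed < 0 || cfg$s_fixed > 1)) {
    abort("invalid config: s_fixed must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$loss_rate_base) ||
      cfg$loss_rate_base < 0 || cfg$loss_rate_base > 1) {
    abort("invalid config: loss_rate_base must lie in [0, 1]")
  }
  if (!is_scalar_number(cfg$expression_noise_sd) || cfg$expression_noise_sd < 0) {
    abort("invalid config: expression_noise_sd must be nonnegative")
  }
  if (!is.list(cfg$effect_sizes)) abort("invalid config: effect_sizes must be a list")
  if (!is_scalar_number(cfg$seed)) abort("invalid config: seed must be an integer")
  invisible(cfg)
}

# split the master seed into one stream seed per sub-generator, so e.g.
# adding tissues does not perturb the copy-number draws
split_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 8)
  names(s) <- c("sensitivity", "expression", "features", "copies", "ase",
                "stops", "go", "spare")
  s
}

#' Simulate observed copy numbers for one orthogroup across the panel
#'
#' Each lineage starts from one ancestral copy. Every polyploidy event
#' multiplies the surviving copies by its factor; after each event every
#' copy is independently lost on the post-event branch with probability
#' `loss_rate_base * (1 - s)`. Lineages without events retain their single
#' copy. With `s = 1` no loss is possible and the observed vector equals
#' the expected one exactly.
#'
#' @param s Latent dosage sensitivity in \[0, 1\].
#' @param histories Lineage histories (tibble `species`, `events`).
#' @param loss_rate_base Per-branch loss probability at `s = 0`.
#' @return A tibble: `species`, `expected`, `observed`.
#' @export
simulate_orthogroup_copies <- function(s, histories, loss_rate_base = 0.4) {
  if (!is_scalar_number(s) || s < 0 || s > 1) abort("s must lie in [0, 1]")
  obs <- simulate_copies_matrix(s, histories, loss_rate_base)
  exp_tbl <- expected_copies_from_histories(histories)
  tibble::tibble(species = histories$species,
                 expected = exp_tbl$expected,
                 observed = as.integer(obs[1, ]))
}

# vectorized over orthogroups: returns n_og x n_species matrix of observed
# counts; consumes the current RNG stream
simulate_copies_matrix <- function(s, histories, loss_rate_base) {
  ev <- parse_events(histories$events)
  n_og <- length(s)
  q <- pmin(pmax(loss_rate_base * (1 - s), 0), 1)
  O <- matrix(0L, n_og, length(ev))
  colnames(O) <- histories$species
  for (j in seq_along(ev)) {
    cnt <- rep(1L, n_og)
    for (m in ev[[j]]) {
      cnt <- rbinom(n_og, cnt * m, 1 - q)
    }
    O[, j] <- cnt
  }
  O
}

#' Simulate allele-specific-expression components for homeolog genes
#'
#' Draws cis (`B`) and trans (`A - B`) components on the log scale with
#' standard deviation `effect_scale * (0.15 + 0.8 * rfpkm_pair)`, so the
#' expected magnitudes `|B|` and `|A - B|` increase with the pair's
#' relative expression difference; `A` is their sum by construction. With
#' `effect_scale = 0` every component is exactly zero.
#'
#' @param rfpkm_pair Vector of pair-average R_FPKM values in \[0, 1\].
#' @param effect_scale Nonnegative magnitude scale.
#' @return A tibble with columns `A`, `B` (one row per input value).
#' @export
simulate_ase <- function(rfpkm_pair, effect_scale = 1) {
  if (any(rfpkm_pair < 0 | rfpkm_pair > 1, na.rm = TRUE)) {
    abort("rfpkm_pair values must lie in [0, 1]")
  }
  n <- length(rfpkm_pair)
  sdv <- effect_scale * (0.15 + 0.8 * rfpkm_pair)
  sdv[is.na(sdv)] <- 0
  B <- rnorm(n, 0, 1) * sdv
  trans <- rnorm(n, 0, 1) * sdv
  tibble::tibble(A = B + trans, B = B)
}

#' Simulate a complete synthetic homeolog study
#'
#' Generates every table the analysis pipeline consumes: a gene-by-tissue
#' FPKM matrix for one focal species (one homeolog pair per orthogroup), a
#' pair list, a per-gene feature table, an orthogroup-by-species
#' copy-number matrix over the panel, ASE records, premature-stop flags, a
#' GO-slim map, and the latent truth. All couplings run through the latent
#' dosage sensitivity `s` (see [synthetic_config()]); the generation is
#' deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @param components Which blocks to generate; dropping unused blocks
#'   (e.g. `copies`, `ase`) speeds up large simulation sweeps.
#' @return A list of class `synthetic_study` with elements `expression`,
#'   `pairs`, `features`, `go`, `copy_numbers`, `og_map`, `tree`,
#'   `histories`, `ase`, `stop_flags`, `truth`, `config`.
#' @export
simulate_study <- function(config = synthetic_config(),
                           components = c("copies", "ase", "stops", "go")) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  validate_synthetic_config(config)
  eff <- config$effect_sizes
  seeds <- split_seeds(config$seed)
  n <- config$n_orthogroups
  nt <- config$n_tissues

  og_id <- sprintf("OG%05d", seq_len(n))
  g1 <- sprintf("g%05da", seq_len(n))
  g2 <- sprintf("g%05db", seq_len(n))
  tissues <- sprintf("tissue%02d", seq_len(nt))

  # latent dosage sensitivity
  set.seed(seeds[["sensitivity"]])
  s <- if (!is.null(config$s_fixed)) rep(config$s_fixed, n) else {
    rbeta(n, config$sensitivity_shape1, config$sensitivity_shape2)
  }

  # expression: lognormal noise around a shared pair mean; copy 2 is
  # downscaled by exp(-balance * (1 - s) * |z|), giving the right-skewed
  # R_FPKM distribution whose strength decreases with s
  set.seed(seeds[["expression"]])
  mu <- rnorm(n, 3, 1)
  tissue_sd <- 0.3 + eff$tau * (1 - s)
  b <- matrix(rnorm(n * nt), n, nt) * tissue_sd
  z <- abs(rnorm(n))
  downscale <- exp(-eff$balance * (1 - s) * z)
  eps1 <- matrix(rnorm(n * nt, 0, config$expression_noise_sd), n, nt)
  eps2 <- matrix(rnorm(n * nt, 0, config$expression_noise_sd), n, nt)
  E1 <- exp(mu + b + eps1)
  E2 <- exp(mu + b + eps2) * downscale
  expression <- tibble::tibble(gene = c(g1, g2))
  em <- rbind(E1, E2)
  for (k in seq_len(nt)) expression[[tissues[k]]] <- em[, k]

  # realized per-pair average R_FPKM drives the downstream couplings
  R <- abs(E1 - E2) / (E1 + E2)
  R[(E1 + E2) == 0] <- NA
  avg_r <- rowMeans(R, na.rm = TRUE)
  avg_r[is.nan(avg_r)] <- 0

  pairs <- tibble::tibble(
    pair_id = og_id, copy1 = g1, copy2 = g2,
    outgroup = sprintf("out%05d", seq_len(n)),
    anchor_evalue = 10^(-runif(n, 10, 120)),
    tandem_array_id = NA_character_
  )
  og_map <- tibble::tibble(pair_id = og_id, og_id = og_id)

  # features: substitution rates scale with realized expression imbalance,
  # structural/functional features with the latent sensitivity itself;
  # tau and dN/dS are drawn as summary values, the per-copy asymmetry
  # (`fate`) disfavours the downscaled copy
  set.seed(seeds[["features"]])
  dn_pair <- exp(-3.5 + eff$dn * avg_r + rnorm(n, 0, 0.35))
  ds_pair <- exp(-1.5 + eff$ds * avg_r + rnorm(n, 0, 0.35))
  fd <- eff$fate / 2
  dn1 <- dn_pair * exp(-fd * 0.5); dn2 <- dn_pair * exp(fd * 0.5)
  protein_pair <- exp(log(350) + eff$protein_length * s + rnorm(n, 0, 0.45))
  pl1 <- pmax(round(protein_pair * exp(fd * 0.2)), 30L)
  pl2 <- pmax(round(protein_pair * exp(-fd * 0.2)), 30L)
  exon <- 1L + rpois(n, exp(0.8 + eff$exon * s))
  pfam <- rpois(n, exp(0.2 + eff$pfam * s))
  ppi <- rpois(n, exp(1.0 + eff$ppi * s))
  lethal <- plogis(-1.5 + eff$lethal * s + rnorm(n, 0, 0.6))
  tau_pair <- pmin(pmax(0.2 + eff$tau * (1 - s) + rnorm(n, 0, 0.12), 0), 1)
  tau1 <- pmin(pmax(tau_pair - fd * 0.08, 0), 1)
  tau2 <- pmin(pmax(tau_pair + fd * 0.08, 0), 1)
  features <- tibble::tibble(
    gene = c(g1, g2),
    dn = c(dn1, dn2),
    ds = c(ds_pair, ds_pair),
    omega = c(dn1, dn2) / c(ds_pair, ds_pair),
    exon_count = c(exon, exon),
    cds_length = 3L * c(pl1, pl2),
    protein_length = c(pl1, pl2),
    pfam_count = c(pfam, pfam),
    ppi_count = c(ppi, ppi),
    lethal_score = c(lethal, lethal),
    tau = c(tau1, tau2)
  )

  study <- list(expression = expression, pairs = pairs, features = features,
                og_map = og_map, tree = config$tree,
                histories = config$wgd_histories,
                truth = tibble::tibble(og_id = og_id, s = s, avg_rfpkm_true = avg_r),
                config = config)

  if ("copies" %in% components) {
    set.seed(seeds[["copies"]])
    O <- simulate_copies_matrix(s, config$wgd_histories, config$loss_rate_base)
    study$copy_numbers <- dplyr::bind_cols(tibble::tibble(og_id = og_id),
                                           tibble::as_tibble(O))
  }
  if ("ase" %in% components) {
    set.seed(seeds[["ase"]])
    stages <- sprintf("stage%d", seq_len(config$n_stages))
    recs <- purrr::map_dfr(stages, function(st) {
      ab <- simulate_ase(rep(avg_r, 2), effect_scale = eff$ase)
      tibble::tibble(gene = c(g1, g2), stage = st, A = ab$A, B = ab$B)
    })
    study$ase <- recs
  }
  if ("stops" %in% components) {
    set.seed(seeds[["stops"]])
    # the downscaled copy (copy 2) is the typically-low copy and accrues
    # premature stops at a higher rate
    p1 <- plogis(-3.2 + eff$stop * avg_r)
    p2 <- plogis(-3.2 + eff$stop * (avg_r + 0.4))
    study$stop_flags <- tibble::tibble(
      gene = c(g1, g2),
      has_premature_stop = as.integer(runif(2 * n) < c(p1, p2))
    )
  }
  if ("go" %in% components) {
    set.seed(seeds[["go"]])
    study$go <- simulate_go_map(og_id, g1, g2, s)
  }
  class(study) <- "synthetic_study"
  study
}

# GO-slim assignment: dosage-linked categories are enriched at high s,
# stress/metabolism categories at low s, the rest uniform
simulate_go_map <- function(og_id, g1, g2, s) {
  cats <- c("translation", "regulation of gene expression, epigenetic",
            "developmental process", "secondary metabolic process",
            "response to biotic stimulus", "transport",
            "signal transduction", "protein metabolism")
  high_s <- cats[1:3]; low_s <- cats[4:5]
  n <- length(og_id)
  k <- sample(1:3, n, replace = TRUE)
  picked <- lapply(seq_len(n), function(i) {
    w <- c(rep(exp(1.2 * s[i]), 3), rep(exp(1.2 * (1 - s[i])), 2), rep(1, 3))
    sample(cats, k[i], prob = w)
  })
  tibble::tibble(
    gene = rep(c(g1, g2), times = rep(lengths(picked), 2)),
    go_slim = rep(unlist(picked), 2)
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d orthogroups, %d tissues, %d species (seed %d)\n",
    nrow(x$pairs), ncol(x$expression) - 1L, nrow(x$histories),
    x$config$seed))
  invisible(x)
}
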