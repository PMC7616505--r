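#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate inputs) or `"real"` (read them from
#'   `inputs`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed; in synthetic mode it seeds the generator, and
#'   in both modes it seeds the deletion-robustness resampling.
#' @param synthetic Named list of [synthetic_config()] overrides.
#' @param inputs Named list of file paths for real mode: `expression` and
#'   `pairs` are required; `features`, `go`, `copy_numbers`,
#'   `wgd_histories`, `tree`, `og_map`, `ase`, `stop_flags` each activate
#'   their analysis when present.
#' @param min_fpkm Optional expression floor for R_FPKM informativeness.
#' @param stop_threshold Balanced/biased cut on average R_FPKM.
#' @param yates Use the Yates continuity correction in chi-squared tests.
#' @param fdr Append BH-adjusted p-values to the association table.
#' @param fate_tissue Focal tissue for the paired high/low-copy feature
#'   comparisons; default the first tissue.
#' @param go_min_n Minimum pairs per GO-slim category.
#' @param robustness_fractions,robustness_replicates Deletion-robustness
#'   grid.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"),
                            out_dir = tempfile("homeobalance_run_"),
                            seed = 1,
                            synthetic = list(),
                            inputs = list(),
                            min_fpkm = 0,
                            stop_threshold = 0.6,
                            yates = FALSE,
                            fdr = FALSE,
                            fate_tissue = NULL,
                            go_min_n = 10,
                            robustness_fractions = c(0.025, 0.05, 0.10, 0.20, 0.40),
                            robustness_replicates = 50) {
  mode <- match.arg(mode)
  if (mode == "real") {
    need <- setdiff(c("expression", "pairs"), names(inputs))
    if (length(need) > 0) {
      abort(sprintf("real mode requires input path(s): %s",
                    paste(need, collapse = ", ")))
    }
  }
  structure(
    list(mode = mode, out_dir = out_dir, seed = seed, synthetic = synthetic,
         inputs = inputs, min_fpkm = min_fpkm,
         stop_threshold = stop_threshold, yates = yates, fdr = fdr,
         fate_tissue = fate_tissue, go_min_n = go_min_n,
         robustness_fractions = robustness_fractions,
         robustness_replicates = robustness_replicates),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full homeolog-balance analysis
#'
#' Orchestrates the end-to-end analysis: (synthetic mode) generate the
#' study and write its input tables; compute per-tissue and average
#' R_FPKM; cross-tissue consistency; feature associations with
#' deletion-robustness; GO-slim summaries; orthogroup dosage profiles and
#' their association with balance; regulatory-divergence associations;
#' premature-stop bias; high/low copy-fate comparisons; and a run
#' manifest. In real mode each optional analysis activates only when its
#' inputs are provided; skipped steps are logged in the manifest.
#' Re-running with an identical config and seed reproduces byte-identical
#' TSVs. On failure, partial outputs are removed.
#'
#' @param config A [pipeline_config()], or a path to a YAML file of its
#'   arguments.
#' @return Invisibly, a named list of the result tables plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  skipped <- list()
  results <- list()
  emit <- function(df, name) {
    p <- file.path(out, name)
    write_table(df, p)
    written <<- c(written, p)
    results[[sub("\\.tsv$", "", name)]] <<- df
  }
  skip <- function(step, why) {
    skipped[[step]] <<- why
    message(sprintf("skipping %s: %s", step, why))
  }

  tryCatch({
    if (config$mode == "synthetic") {
      scfg <- do.call(synthetic_config,
                      utils::modifyList(list(seed = config$seed), config$synthetic))
      study <- simulate_study(scfg)
      written <- c(written, write_study(study, file.path(out, "inputs")))
      expr <- study$expression; pairs <- study$pairs
      features <- study$features; go <- study$go
      copy_numbers <- study$copy_numbers; histories <- study$histories
      tree <- study$tree; og_map <- study$og_map
      ase <- study$ase; stops <- study$stop_flags
    } else {
      inp <- config$inputs
      expr <- read_expression(inp$expression)
      pairs <- read_pairs(inp$pairs)
      features <- if (!is.null(inp$features)) read_features(inp$features)
      go <- if (!is.null(inp$go)) read_go_map(inp$go)
      copy_numbers <- if (!is.null(inp$copy_numbers)) read_copy_numbers(inp$copy_numbers)
      histories <- if (!is.null(inp$wgd_histories)) read_wgd_histories(inp$wgd_histories)
      tree <- if (!is.null(inp$tree)) ape::read.tree(inp$tree)
      og_map <- if (!is.null(inp$og_map)) {
        read_checked(inp$og_map,
                     readr::cols(.default = readr::col_character()),
                     c("pair_id", "og_id"), "orthogroup map")
      }
      ase <- if (!is.null(inp$ase)) read_ase(inp$ase)
      stops <- if (!is.null(inp$stop_flags)) read_stop_flags(inp$stop_flags)
      if (!is.null(copy_numbers) && !is.null(tree)) {
        miss <- setdiff(setdiff(names(copy_numbers), "og_id"), tree$tip.label)
        if (length(miss) > 0) {
          abort(sprintf("copy-number species absent from tree: %s",
                        paste(head(miss, 5), collapse = ", ")))
        }
      }
    }

    pairs <- dedup_tandem_anchor_pairs(pairs)
    long <- rfpkm_by_tissue(pairs, expr, min_fpkm = config$min_fpkm)
    profiles <- pair_balance(pairs, expr, min_fpkm = config$min_fpkm)
    emit(long, "rfpkm_by_tissue.tsv")
    emit(profiles, "balance_profiles.tsv")
    if (length(unique(long$tissue)) >= 2) {
      emit(cross_tissue_consistency(long), "cross_tissue_consistency.tsv")
    } else skip("cross_tissue_consistency", "fewer than two tissues")

    if (!is.null(features)) {
      assoc <- feature_association_table(profiles, features, pairs,
                                         fdr = config$fdr)
      emit(assoc, "association_table.tsv")
      emit(robustness_by_deletion(profiles, features, pairs,
                                  fractions = config$robustness_fractions,
                                  replicates = config$robustness_replicates,
                                  seed = config$seed),
           "robustness.tsv")
    } else skip("association", "no feature table provided")

    if (!is.null(features) && !is.null(go)) {
      emit(go_slim_summary(profiles, pairs, go, min_n = config$go_min_n),
           "go_slim_summary.tsv")
    } else if (is.null(go)) skip("go_slim_summary", "no GO-slim map provided")

    if (!is.null(copy_numbers) && !is.null(histories) && !is.null(tree)) {
      ogp <- og_dosage_profiles(copy_numbers, histories, tree)
      emit(ogp, "dosage_profiles.tsv")
      if (!is.null(og_map)) {
        emit(dosage_balance_association(profiles, og_map, ogp),
             "dosage_association.tsv")
      } else skip("dosage_association", "no pair-to-orthogroup map provided")
    } else {
      skip("dosage", "copy numbers, polyploidy histories or tree missing")
    }

    if (!is.null(ase)) {
      emit(rfpkm_regulatory_association(profiles, pairs, ase),
           "regulatory_association.tsv")
    } else skip("regulatory_association", "no ASE records provided")

    if (!is.null(stops)) {
      emit(stop_codon_bias(profiles, pairs, stops,
                           threshold = config$stop_threshold,
                           correct = config$yates),
           "stop_codon_bias.tsv")
    } else skip("stop_codon_bias", "no premature-stop flags provided")

    assignments <- classify_copies(pairs, expr)
    emit(assignments, "fate_assignments.tsv")
    fate_tissue <- config$fate_tissue %||% setdiff(names(expr), "gene")[1]
    focal <- assignments[assignments$tissue == fate_tissue, ]
    if (!is.null(features) && nrow(focal) >= 2) {
      emit(paired_feature_comparison(focal, features), "fate_comparison.tsv")
    } else skip("fate_comparison", "no feature table or too few ranked pairs")
    if (!is.null(stops)) {
      emit(stop_fate_comparison(assignments, stops, correct = config$yates),
           "fate_stop_comparison.tsv")
    } else skip("fate_stop_comparison", "no premature-stop flags provided")

    manifest <- list(
      package = "homeobalance",
      version = as.character(utils::packageVersion("homeobalance")),
      mode = config$mode,
      seed = config$seed,
      n_pairs = nrow(pairs),
      n_tissues = length(setdiff(names(expr), "gene")),
      row_counts = lapply(results, nrow),
      skipped = if (length(skipped)) skipped else NULL
    )
    mp <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mp)
    results$manifest <- manifest
    invisible(results)
  }, error = function(e) {
    unlink(written)
    abort(sprintf("pipeline failed (partial outputs removed): %s",
                  conditionMessage(e)))
  })
}
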