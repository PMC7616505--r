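# Tabular I/O: TSV everywhere, "." for missing, UTF-8, LF line endings.
# Floats are serialized with 12 significant digits so re-runs are
# byte-identical; every writer's output is re-readable by the same reader.

format_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- sprintf("%.12g", x)
  } else {
    out <- as.character(x)
  }
  out[is.na(x)] <- "."
  out
}

#' Write a table as TSV with "." for missing values
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `df`, invisibly.
#' @export
write_table <- function(df, path) {
  out <- purrr::map(df, format_cell)
  txt <- c(paste(names(df), collapse = "\t"),
           do.call(paste, c(out, sep = "\t")))
  con <- file(path, open = "wb")  # binary mode pins LF endings
  on.exit(close(con))
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(df)
}

# read a TSV against a readr col spec; schema violations name the column
read_checked <- function(path, col_types, required, what) {
  df <- suppressWarnings(
    readr::read_tsv(path, na = ".", col_types = col_types,
                    progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf("%s: invalid value in %s at row %d, column %d (expected %s)",
                  path, what, p$row, p$col, p$expected))
  }
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: %s is missing column(s): %s", path, what,
                  paste(miss, collapse = ", ")))
  }
  df
}

#' Read / write an expression matrix (gene by tissue FPKM)
#'
#' First column `gene`, one numeric column per tissue.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  df <- read_checked(path, readr::cols(gene = readr::col_character(),
                                       .default = readr::col_double()),
                     "gene", "expression matrix")
  expression_matrix(df)  # validates duplicates / negativity
  df
}

#' Read a homeolog pair list
#'
#' Columns: `copy1`, `copy2`, optional `pair_id`, `outgroup`,
#' `anchor_evalue`, `tandem_array_id` (`.` for none).
#'
#' @param path File path.
#' @return A tibble with a `pair_id` column.
#' @export
read_pairs <- function(path) {
  df <- read_checked(path, readr::cols(.default = readr::col_character()),
                     c("copy1", "copy2"), "pair list")
  if ("anchor_evalue" %in% names(df)) {
    val <- suppressWarnings(as.numeric(df$anchor_evalue))
    bad <- which(!is.na(df$anchor_evalue) & is.na(val))
    if (length(bad) > 0) {
      abort(sprintf("%s: invalid value in pair list at row %d, column anchor_evalue",
                    path, bad[1]))
    }
    df$anchor_evalue <- val
  }
  ensure_pair_id(df)
}

#' Read a per-gene feature table
#'
#' A `gene` column plus any of: `dn`, `ds`, `omega`, `exon_count`,
#' `cds_length`, `protein_length`, `pfam_count`, `ppi_count`,
#' `lethal_score`, `tau`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_features <- function(path) {
  df <- read_checked(path, readr::cols(gene = readr::col_character(),
                                       .default = readr::col_double()),
                     "gene", "feature table")
  # where dn, ds and omega are all supplied they must agree
  if (all(c("dn", "ds", "omega") %in% names(df))) {
    ok <- is.na(df$dn) | is.na(df$ds) | is.na(df$omega) | df$ds <= 0 |
      abs(df$omega - df$dn / df$ds) < 1e-6
    if (!all(ok)) {
      abort(sprintf("%s: omega inconsistent with dn/ds for gene(s): %s", path,
                    paste(head(df$gene[!ok], 5), collapse = ", ")))
    }
  }
  df
}

#' Read an orthogroup-by-species copy-number matrix
#'
#' @param path File path.
#' @return A tibble with `og_id` plus one integer column per species.
#' @export
read_copy_numbers <- function(path) {
  read_checked(path, readr::cols(og_id = readr::col_character(),
                                 .default = readr::col_integer()),
               "og_id", "copy-number matrix")
}

#' Read lineage polyploidy histories
#'
#' TSV with columns `species` and `events`, the latter a comma-separated
#' multiplier list such as `3,2,2,3` (`.` for none).
#'
#' @param path File path.
#' @return A tibble with `events` parsed to a list-column.
#' @export
read_wgd_histories <- function(path) {
  df <- read_checked(path, readr::cols(species = readr::col_character(),
                                       events = readr::col_character()),
                     c("species", "events"), "polyploidy histories")
  df$events <- parse_events(df$events)
  df
}

#' Write lineage polyploidy histories
#'
#' @param histories Tibble with `species` and `events` list-column.
#' @param path Output path.
#' @export
write_wgd_histories <- function(histories, path) {
  ev <- vapply(parse_events(histories$events), function(e) {
    if (length(e) == 0) "." else paste(e, collapse = ",")
  }, character(1))
  write_table(tibble::tibble(species = histories$species, events = ev), path)
}

#' Read allele-specific-expression records
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `stage`, `A`, `B`.
#' @export
read_ase <- function(path) {
  read_checked(path, readr::cols(gene = readr::col_character(),
                                 stage = readr::col_character(),
                                 A = readr::col_double(),
                                 B = readr::col_double()),
               c("gene", "stage", "A", "B"), "ASE records")
}

#' Read premature-stop flags
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `has_premature_stop`.
#' @export
read_stop_flags <- function(path) {
  read_checked(path, readr::cols(gene = readr::col_character(),
                                 has_premature_stop = readr::col_integer()),
               c("gene", "has_premature_stop"), "stop flags")
}

#' Read a GO-slim map
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `go_slim`.
#' @export
read_go_map <- function(path) {
  read_checked(path, readr::cols(gene = readr::col_character(),
                                 go_slim = readr::col_character()),
               c("gene", "go_slim"), "GO-slim map")
}

#' Write a synthetic study to disk in the real-mode input formats
#'
#' Emits the same TSV/newick files the real-mode pipeline reads, so
#' synthetic and real data are interchangeable.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write_table(df, p)
    paths <<- c(paths, p)
  }
  emit(study$expression, "expression.tsv")
  emit(study$pairs, "pairs.tsv")
  emit(study$features, "features.tsv")
  emit(study$og_map, "og_map.tsv")
  if (!is.null(study$copy_numbers)) emit(study$copy_numbers, "copy_numbers.tsv")
  if (!is.null(study$ase)) emit(study$ase, "ase.tsv")
  if (!is.null(study$stop_flags)) emit(study$stop_flags, "stop_flags.tsv")
  if (!is.null(study$go)) emit(study$go, "go_map.tsv")
  write_wgd_histories(study$histories, file.path(dir, "wgd_histories.tsv"))
  paths <- c(paths, file.path(dir, "wgd_histories.tsv"))
  tp <- file.path(dir, "species_tree.nwk")
  ape::write.tree(study$tree, file = tp)
  paths <- c(paths, tp)
  invisible(paths)
}
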