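#' Run the full analysis pipeline over a database and query set
#'
#' Composes every stage end to end: builds (or loads) the pentapeptide
#' frequency table, computes each query protein's profile, height field,
#' ELIS tree and entropy curves, assembles the cohort correlation matrix,
#' and scans for the stable CSA structure.  All artifacts are written under
#' `out_dir` as the module TSV/JSON formats; every file carries a hash of
#' the run configuration, and a rerun with identical inputs and
#' configuration reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created; existing files overwritten).
#' @param db_fasta FASTA of the non-redundant frequency database
#'   (required unless `table_file` is given).
#' @param table_file Optional pre-built table from [write_freq_table()].
#' @param query_fasta Optional FASTA of query proteins; defaults to the
#'   database records themselves.
#' @param delta Hamming radius (default 1).
#' @param min_len,max_len Length bounds applied to the database records.
#' @param thresholds CSA threshold schedule (see [stability_scan()]).
#' @param min_proteins,min_pair Cohort filters (see [build_level_vectors()]
#'   and [correlation_matrix()]).
#' @param difference Entropy-derivative scheme.
#' @param verbose Emit progress messages (per 100 proteins).
#' @return `out_dir`, invisibly, with the written file paths attached as
#'   attribute `files`.
#' @export
run_pipeline <- function(out_dir, db_fasta = NULL, table_file = NULL,
                         query_fasta = NULL, delta = 1L,
                         min_len = 50L, max_len = 400L,
                         thresholds = c(0.9, 0.7, 0.5, 0.3, 0.1,
                                        0.05, 0.02, 0.01, 0.001),
                         min_proteins = 10L, min_pair = 10L,
                         difference = "forward", verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(db_fasta) && is.null(table_file))
    stop("either 'db_fasta' or 'table_file' is required")
  for (f in c(db_fasta, table_file, query_fasta))
    if (!file.exists(f)) stop("input file not found: ", f)
  if (is.null(db_fasta) && is.null(query_fasta))
    stop("'query_fasta' is required when only a table file is given")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(delta = delta, min_len = min_len, max_len = max_len,
              thresholds = paste(thresholds, collapse = ","),
              min_proteins = min_proteins, min_pair = min_pair,
              difference = difference)
  cfg_lines <- paste0(names(cfg), ": ", unlist(cfg))
  cfg_path <- file.path(out_dir, "config.txt")
  write_lines_utf8(cfg_lines, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  stamp <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    write_lines_utf8(c(paste0("# config_hash: ", hash), lines), path)
    path
  }
  files <- character(0)
  stage <- "setup"
  aborted <- TRUE
  on.exit({
    if (aborted)
      try(write_lines_utf8(paste0("aborted at stage: ", stage),
                           file.path(out_dir, "ABORTED")), silent = TRUE)
  })
  if (file.exists(file.path(out_dir, "ABORTED")))
    unlink(file.path(out_dir, "ABORTED"))

  stage <- "build-db"
  if (!is.null(table_file)) {
    say("loading frequency table from ", table_file)
    table <- read_freq_table(table_file)
    db_records <- NULL
  } else {
    say("scanning database ", db_fasta)
    db_records <- scan_database(db_fasta, min_len = min_len,
                                max_len = max_len)
    table <- count_pentapeptides(db_records)
    say("counted ", table$n_fragments_total, " windows over ",
        table$n_sequences, " sequences")
  }
  tab_path <- file.path(out_dir, "table.tsv")
  write_freq_table(table, tab_path)
  files <- c(files, stamp(tab_path))

  stage <- "queries"
  queries <- if (!is.null(query_fasta)) {
    scan_database(query_fasta, min_len = 1L, max_len = .Machine$integer.max)
  } else db_records
  if (is.null(queries) || nrow(queries) == 0L)
    stop("no query sequences to analyse")

  prot_dir <- file.path(out_dir, "proteins")
  dir.create(prot_dir, showWarnings = FALSE)
  cohort <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    id <- queries$id[i]
    stage <- paste0("per-protein analysis (record ", id, ")")
    fit <- tryCatch(
      anis(queries[i, ], table, delta = delta, difference = difference),
      error = function(e) stop("record '", id, "': ",
                               conditionMessage(e), call. = FALSE))
    base <- file.path(prot_dir, id)
    write_profile(fit$profile, paste0(base, ".profile.tsv"))
    write_height_field(fit$field, paste0(base, ".height.tsv"))
    write_elis_tree(fit$tree, paste0(base, ".tree.json"))
    write_entropy_curves(fit$curves, paste0(base, ".curves.tsv"))
    files <- c(files, vapply(paste0(base, c(".profile.tsv", ".height.tsv",
                                            ".tree.json", ".curves.tsv")),
                             stamp, ""))
    cohort[[i]] <- fit$curves
    if (verbose && i %% 100L == 0L)
      message("  analysed ", i, "/", nrow(queries), " proteins")
  }

  stage <- "cohort"
  scan <- csa_scan(cohort, thresholds = thresholds,
                   min_proteins = min_proteins, min_pair = min_pair)
  mat_path <- file.path(out_dir, "cohort_matrix.tsv")
  write_cohort_matrix(scan$matrix, mat_path)
  mask_t <- if (scan$result$stable) scan$result$threshold
            else min(thresholds)
  mask_path <- file.path(out_dir, "mask_stable.tsv")
  write_mask(threshold_mask(scan$matrix, mask_t), mask_path)
  csa_path <- file.path(out_dir, "csa.tsv")
  write_csa(scan$result, csa_path)
  files <- c(files, vapply(c(mat_path, mask_path, csa_path), stamp, ""))
  say(if (scan$result$stable)
        paste0("CSA structure stable from threshold ", scan$result$threshold)
      else "CSA structure did not stabilize over the schedule")

  aborted <- FALSE
  invisible(structure(out_dir, files = unname(c(cfg_path, files))))
}
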