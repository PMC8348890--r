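#' Read and filter a protein sequence collection
#'
#' Reads a multi-record protein FASTA file, upper-cases the residues, and
#' keeps the records whose length falls inside `[min_len, max_len]`
#' (inclusive).  The default bounds, 50--400 residues, match the size window
#' commonly used when assembling non-redundant frequency databases.
#'
#' The method presumes a non-redundant input set; redundancy reduction
#' (e.g. 90\% identity clustering) is deliberately not performed here.
#' Duplicate record identifiers are an error.
#'
#' @param fasta_source Path to a FASTA file (wrapped or unwrapped lines).
#' @param min_len,max_len Inclusive residue-count bounds.
#' @return A `data.frame` with columns `id`, `residues`, `length`, one row
#'   per retained record, in input order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDEFGHIKLMNPQRSTVWY", ">p2", "ACDEF"), fa)
#' scan_database(fa, min_len = 5, max_len = 10)
#' @export
scan_database <- function(fasta_source, min_len = 50L, max_len = 400L) {
  if (!is_count(min_len) || !is_count(max_len) || min_len < 1 ||
      min_len > max_len)
    stop("require 1 <= min_len <= max_len")
  if (!is.character(fasta_source) || length(fasta_source) != 1L)
    stop("'fasta_source' must be a single file path")
  if (!file.exists(fasta_source))
    stop("FASTA file not found: ", fasta_source)
  aa <- tryCatch(
    Biostrings::readAAStringSet(fasta_source),
    error = function(e) stop("malformed FASTA '", fasta_source, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  keep <- Biostrings::width(aa) >= min_len & Biostrings::width(aa) <= max_len
  out <- data.frame(id = ids[keep], residues = unname(seqs[keep]),
                    length = Biostrings::width(aa)[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    warning("no records within length bounds [", min_len, ", ", max_len, "]")
  out
}

#' Count overlapping pentapeptides over a record set
#'
#' Scans every record with a sliding window of five residues advancing one
#' position at a time (neighbouring fragments overlap by four residues) and
#' tallies the occurrence count phi(A) of each distinct pentapeptide A.
#' Windows containing a residue outside the canonical 20-letter alphabet
#' (X, B, Z, U, J, O, gaps, stops) are skipped; the number of skipped
#' windows is reported in the result and via a message.
#'
#' @param records A `data.frame` as returned by [scan_database()] (columns
#'   `id` and `residues`), or a character vector of sequences.  Records
#'   shorter than five residues contribute nothing.
#' @return An object of class `penta_table`: a list with `counts` (named
#'   integer vector, keys sorted lexicographically), `n_sequences`,
#'   `n_fragments_total` (number of counted windows, equal to
#'   `sum(counts)`), `n_windows_skipped`, `length_bounds` and `alphabet`.
#' @examples
#' tab <- count_pentapeptides(c(p1 = "AAAAAA"))
#' tab$counts  # AAAAAA contains AAAAA twice
#' @export
count_pentapeptides <- function(records) {
  seqs <- if (is.data.frame(records)) records$residues else as.character(records)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  windows <- character(0)
  for (s in seqs[lens >= 5L]) {
    n <- nchar(s)
    windows <- c(windows, substring(s, 1:(n - 4L), 5:n))
  }
  bad_pat <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  valid <- !grepl(bad_pat, windows)
  n_skipped <- sum(!valid)
  if (n_skipped > 0L)
    message(n_skipped, " window(s) containing non-canonical residues skipped")
  counts <- if (any(valid)) {
    tb <- table(windows[valid])
    stats::setNames(as.integer(tb), names(tb))
  } else stats::setNames(integer(0), character(0))
  lb <- if (length(lens)) c(min(lens), max(lens)) else c(NA_integer_, NA_integer_)
  new_penta_table(counts, n_sequences = length(seqs),
                  length_bounds = lb, n_windows_skipped = n_skipped)
}

#' @noRd
new_penta_table <- function(counts, n_sequences, length_bounds,
                            n_windows_skipped = 0L) {
  counts <- counts[order(names(counts), method = "radix")]
  if (length(counts) == 0L) counts <- stats::setNames(integer(0), character(0))
  structure(list(counts = counts,
                 n_sequences = as.integer(n_sequences),
                 n_fragments_total = as.integer(sum(counts)),
                 n_windows_skipped = as.integer(n_windows_skipped),
                 length_bounds = as.integer(length_bounds),
                 alphabet = AA_ALPHABET,
                 index = list2env(as.list(counts), hash = TRUE,
                                  size = max(29L, length(counts)))),
            class = "penta_table")
}

#' @export
print.penta_table <- function(x, ...) {
  cat("Pentapeptide frequency table\n")
  cat("  distinct pentapeptides:", length(x$counts), "\n")
  cat("  windows counted:       ", x$n_fragments_total, "\n")
  cat("  sequences:             ", x$n_sequences,
      sprintf(" (lengths %s-%s)\n", x$length_bounds[1], x$length_bounds[2]))
  if (x$n_windows_skipped > 0L)
    cat("  windows skipped:       ", x$n_windows_skipped, "\n")
  invisible(x)
}

#' Enumerate the Hamming ball around a pentapeptide
#'
#' Returns every 5-letter fragment over the canonical 20-letter alphabet
#' whose Hamming distance to `fragment` is at most `delta`, including the
#' fragment itself.  Ball sizes follow the closed form
#' \eqn{\sum_{d=0}^{\delta} \binom{5}{d} 19^d}: 1, 96, 3706, 72296 for
#' delta 0..3.
#'
#' @param fragment A 5-letter pentapeptide string.
#' @param delta Maximum Hamming distance, an integer in 0..3.
#' @return Character vector of fragments (the exact-match fragment first,
#'   then distance-ordered).
#' @examples
#' length(hamming_neighbors("ACDEF", 1))  # 96
#' @export
hamming_neighbors <- function(fragment, delta = 1L) {
  fragment <- toupper(fragment)
  if (!is.character(fragment) || length(fragment) != 1L ||
      nchar(fragment) != 5L)
    stop("'fragment' must be a single 5-letter string")
  if (!is_count(delta) || delta < 0 || delta > 3)
    stop("'delta' must be an integer in 0..3")
  letters5 <- strsplit(fragment, "")[[1]]
  out <- fragment
  for (d in seq_len(delta)) {
    combos <- utils::combn(5L, d)
    for (k in seq_len(ncol(combos))) {
      pos <- combos[, k]
      alts <- lapply(pos, function(p) setdiff(AA_ALPHABET, letters5[p]))
      grid <- as.matrix(expand.grid(alts, KEEP.OUT.ATTRS = FALSE,
                                    stringsAsFactors = FALSE))
      base <- matrix(letters5, nrow = nrow(grid), ncol = 5L, byrow = TRUE)
      base[, pos] <- grid
      out <- c(out, paste0(base[, 1L], base[, 2L], base[, 3L],
                           base[, 4L], base[, 5L]))
    }
  }
  out
}

#' Total frequency of a pentapeptide over its Hamming ball
#'
#' Computes \eqn{\Phi(A) = \sum_{J : d(A,J) \le \delta} \phi(J)}, the sum of
#' database occurrence counts over all pentapeptides within Hamming distance
#' `delta` of `fragment`.  At `delta = 0` this is the plain count
#' \eqn{\phi(A)}; the default `delta = 1` sums over the 96-member ball.
#' The sum is evaluated by explicit ball enumeration against the exact-count
#' table.
#'
#' @param table A `penta_table` from [count_pentapeptides()] or
#'   [read_freq_table()].
#' @param fragment A 5-letter pentapeptide.
#' @param delta Maximum Hamming distance (0..3), default 1.
#' @return Non-negative integer total frequency.  A fragment containing a
#'   non-alphabet character yields 0 with a warning.
#' @export
total_frequency <- function(table, fragment, delta = 1L) {
  stopifnot(inherits(table, "penta_table"))
  fragment <- toupper(fragment)
  if (!is.character(fragment) || length(fragment) != 1L ||
      nchar(fragment) != 5L)
    stop("'fragment' must be a single 5-letter string")
  if (grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), fragment)) {
    warning("fragment '", fragment,
            "' contains non-alphabet characters; total frequency 0")
    return(0L)
  }
  ball <- hamming_neighbors(fragment, delta)
  sum(unlist(mget(ball, envir = table$index, ifnotfound = 0L),
             use.names = FALSE))
}

#' Write a pentapeptide frequency table to TSV
#'
#' Serializes a `penta_table` as a UTF-8 TSV file: `#`-prefixed header lines
#' carrying the metadata, then `pentapeptide<TAB>count` rows with keys in
#' lexicographic order (reproducible diffs).  [read_freq_table()] inverts
#' the format exactly.
#'
#' @param table A `penta_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(inherits(table, "penta_table"))
  hdr <- c("# anis pentapeptide frequency table",
           paste0("# n_sequences: ", table$n_sequences),
           paste0("# n_fragments_total: ", table$n_fragments_total),
           paste0("# n_windows_skipped: ", table$n_windows_skipped),
           paste0("# length_bounds: ", table$length_bounds[1], " ",
                  table$length_bounds[2]))
  body <- paste0(names(table$counts), "\t", table$counts)
  write_lines_utf8(c(hdr, body), path)
}

#' Read a pentapeptide frequency table from TSV
#'
#' @param path File produced by [write_freq_table()].
#' @return A `penta_table`; the round trip `read(write(T))` reproduces `T`
#'   including metadata.
#' @export
read_freq_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  hdr <- lines[is_hdr]
  body <- lines[!is_hdr]
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) != 1L) stop("table file missing header '", key, "'")
    sub(paste0("^# ", key, ": "), "", ln)
  }
  n_seq <- as.integer(get_meta("n_sequences"))
  n_frag <- as.integer(get_meta("n_fragments_total"))
  n_skip <- as.integer(get_meta("n_windows_skipped"))
  lb <- as.integer(strsplit(get_meta("length_bounds"), " ")[[1]])
  if (length(body) == 0L) {
    counts <- stats::setNames(integer(0), character(0))
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) != 2L)
    if (length(bad))
      stop("malformed table row at line ", which(!is_hdr)[bad[1]],
           ": expected 'pentapeptide<TAB>count'")
    keys <- vapply(parts, `[[`, "", 1L)
    badkey <- which(nchar(keys) != 5L |
                      grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                            keys))
    if (length(badkey))
      stop("invalid pentapeptide key '", keys[badkey[1]], "' at line ",
           which(!is_hdr)[badkey[1]])
    vals <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    badval <- which(is.na(vals) | vals < 0L)
    if (length(badval))
      stop("invalid count at line ", which(!is_hdr)[badval[1]])
    counts <- stats::setNames(vals, keys)
  }
  if (sum(counts) != n_frag)
    stop("corrupt table: counts sum to ", sum(counts),
         " but header declares n_fragments_total ", n_frag)
  tab <- new_penta_table(counts, n_sequences = n_seq, length_bounds = lb,
                         n_windows_skipped = n_skip)
  tab
}
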