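#' Total-frequency profile of one protein
#'
#' Maps a protein sequence \eqn{I = i_1 \ldots i_N} to the function
#' \eqn{f_I(j) = \Phi(I_j)}: for every overlapping pentapeptide, indexed by
#' its central residue \eqn{j = 3, \ldots, N-2}, the Hamming-ball total
#' frequency looked up in a database table.  Windows containing
#' non-canonical residues receive frequency 0 (with a count of such windows
#' attached to the result).
#'
#' @param record A single sequence: a character string, or a one-row
#'   `data.frame` with columns `id` and `residues` (as from
#'   [scan_database()]).
#' @param table A `penta_table`.
#' @param delta Hamming radius for the total frequency (default 1).
#' @return An object of class `freq_profile`: list with `id`, `residues`,
#'   `n` (sequence length N), `positions` (central residues 3..N-2) and
#'   `values` (the N-4 total frequencies).
#' @export
frequency_profile <- function(record, table, delta = 1L) {
  stopifnot(inherits(table, "penta_table"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    id <- record$id
    seqc <- record$residues
  } else {
    id <- if (!is.null(names(record))) names(record)[1] else "query"
    seqc <- as.character(record)[1]
  }
  seqc <- toupper(seqc)
  n <- nchar(seqc)
  if (n < 5L) stop("sequence '", id, "' shorter than 5 residues (N=", n, ")")
  windows <- substring(seqc, 1:(n - 4L), 5:n)
  bad_pat <- paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
  valid <- !grepl(bad_pat, windows)
  vals <- numeric(length(windows))
  if (any(valid)) {
    vals[valid] <- if (delta <= 1L)
      phi_ball_batch(windows[valid], table, delta)
    else
      vapply(windows[valid], total_frequency, numeric(1),
             table = table, delta = delta)
  }
  structure(list(id = id, residues = seqc, n = n,
                 positions = 3:(n - 2L), values = unname(vals),
                 delta = as.integer(delta),
                 n_windows_skipped = sum(!valid)),
            class = "freq_profile")
}

# Log-domain smoothed distribution: log F(x) by log-sum-exp over the
# kernel terms.  `d2` is the (x, j) matrix of (x - j)^2 / (2 y^2).  Shared
# by smoothed_profile() and height_field() so both produce bitwise-equal
# log values.
#' @noRd
smooth_log_core <- function(d2, f, y) {
  logf <- ifelse(f > 0, log(f), -Inf)
  lt <- (-d2 + matrix(logf, nrow(d2), length(logf), byrow = TRUE)) -
    log(y * sqrt(2 * pi))
  row_logsumexp(lt)
}

# Vectorized Hamming-ball totals for many windows at once (delta <= 1).
# Summing phi over every single-position substitution with all 20 letters
# counts the original window five extra times, so Phi = sum - 4 * phi(W).
# Agrees exactly with per-window ball enumeration; asserted in tests.
#' @noRd
phi_ball_batch <- function(windows, table, delta) {
  look <- function(keys)
    unlist(mget(keys, envir = table$index, ifnotfound = 0L),
           use.names = FALSE)
  own <- look(windows)
  if (delta == 0L) return(own)
  tot <- -4 * own
  for (p in 1:5) {
    pre <- substr(windows, 1L, p - 1L)
    post <- substr(windows, p + 1L, 5L)
    for (a in AA_ALPHABET)
      tot <- tot + look(paste0(pre, a, post))
  }
  tot
}

#' @noRd
new_freq_profile <- function(values, id = "synthetic", n = length(values) + 4L,
                             delta = NA_integer_) {
  stopifnot(length(values) == n - 4L, all(values >= 0))
  structure(list(id = id, residues = NA_character_, n = as.integer(n),
                 positions = 3:(n - 2L), values = as.numeric(values),
                 delta = delta, n_windows_skipped = 0L),
            class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("Total-frequency profile of '", x$id, "' (N = ", x$n, ", delta = ",
      x$delta, ")\n", sep = "")
  cat("  ", length(x$values), " values over central residues ",
      x$positions[1], "..", x$positions[length(x$positions)], "\n", sep = "")
  invisible(x)
}

#' Gaussian kernel
#'
#' The normalized Gaussian \eqn{g(x, y) = \frac{1}{y\sqrt{2\pi}}
#' e^{-x^2/(2y^2)}} used to smooth frequency profiles; `y` is the
#' half-width (scale) parameter.
#'
#' @param x Real offset(s).
#' @param y Positive half-width.
#' @return Kernel value(s); symmetric in `x`, maximal at `x = 0`, unit
#'   integral over the real line.
#' @export
gaussian_kernel <- function(x, y) {
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y <= 0)
    stop("'y' must be a single positive number")
  exp(-x^2 / (2 * y^2)) / (y * sqrt(2 * pi))
}

#' Gaussian-smoothed total-frequency distribution
#'
#' Evaluates \eqn{F_I(x) = \sum_{j=3}^{N-2} f_I(j)\, g(x - j, y)} on the
#' integer grid \eqn{x = 1, \ldots, N}.  No renormalization is applied near
#' the sequence ends: the sum runs only over existing profile positions, so
#' F decays toward the termini.
#'
#' Two evaluations are stored: `values`, the plain sum with kernel terms
#' beyond `truncate * y` positions dropped (relative dropped mass below
#' `exp(-truncate^2/2)`, about 1e-14 at the default 8), and `log_values`,
#' the full sum evaluated in the log domain by log-sum-exp.  The log form
#' stays meaningful where the linear sum underflows to zero and is what the
#' inscribed-height minimization consumes.
#'
#' @param profile A `freq_profile`.
#' @param y Positive smoothing half-width.
#' @param truncate Kernel support radius in units of `y` for the linear
#'   evaluation; `Inf` disables truncation.
#' @return Object of class `smoothed_profile`: list with `id`, `n`, `y`,
#'   `x` (grid 1..N), `values` and `log_values`.
#' @export
smoothed_profile <- function(profile, y, truncate = 8) {
  stopifnot(inherits(profile, "freq_profile"))
  if (!is.numeric(y) || length(y) != 1L || is.na(y) || y <= 0)
    stop("'y' must be a single positive number")
  n <- profile$n
  x <- seq_len(n)
  j <- profile$positions
  f <- profile$values
  d2 <- outer(x, j, "-")^2 / (2 * y^2)
  g <- exp(-d2) / (y * sqrt(2 * pi))
  if (is.finite(truncate)) g[d2 > truncate^2 / 2] <- 0
  vals <- as.vector(g %*% f)
  logvals <- smooth_log_core(d2, f, y)
  structure(list(id = profile$id, n = n, y = y, x = x,
                 values = vals, log_values = logvals),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat("Smoothed profile of '", x$id, "' at scale y = ", x$y,
      " (N = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Export a frequency profile (and optionally its smoothed form) to TSV
#'
#' Writes `position<TAB>f` rows (and, when `smoothed` is supplied,
#' `position<TAB>F` rows) preceded by `#` metadata lines carrying the
#' record id, delta and scale.
#'
#' @param profile A `freq_profile`.
#' @param path Output path.
#' @param smoothed Optional `smoothed_profile` for the same record.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, smoothed = NULL) {
  stopifnot(inherits(profile, "freq_profile"))
  hdr <- c(paste0("# id: ", profile$id),
           paste0("# delta: ", profile$delta))
  body <- paste0(profile$positions, "\t",
                 formatC(profile$values, format = "g", digits = 15))
  lines <- c(hdr, "# column: position\tf", body)
  if (!is.null(smoothed)) {
    stopifnot(inherits(smoothed, "smoothed_profile"))
    lines <- c(lines,
               paste0("# y: ", smoothed$y),
               "# column: position\tF",
               paste0(smoothed$x, "\t",
                      formatC(smoothed$values, format = "g", digits = 15)))
  }
  write_lines_utf8(lines, path)
}
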