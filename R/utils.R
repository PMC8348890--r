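# Internal helpers shared across modules.

# The 20 canonical amino-acid residues, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

# Row-wise log-sum-exp of a matrix, -Inf rows allowed (all-excluded terms).
# max.col with ties.method = "first" keeps the evaluation deterministic.
#' @noRd
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

# Column-wise minima of a matrix (exact, deterministic).
#' @noRd
col_mins <- function(m) {
  tm <- t(m)
  idx <- max.col(-tm, ties.method = "first")
  tm[cbind(seq_len(nrow(tm)), idx)]
}

# Strict local maxima of a numeric vector under the shared plateau rule:
# a run of equal values flanked by strictly smaller values counts once, at
# the midpoint of the run (rounded down).  With `endpoints = TRUE` a
# boundary run qualifies when it is strictly above its single neighbour
# (the missing side counts as smaller); with FALSE boundary runs never
# qualify.  `positive_only` drops maxima with value <= 0 (used for height
# rows, where a zero "maximum" is meaningless).
#' @noRd
local_maxima <- function(v, endpoints = TRUE, positive_only = FALSE) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- if (i == 1L) endpoints else r$values[i - 1L] < r$values[i]
    right_ok <- if (i == k) endpoints else r$values[i + 1L] < r$values[i]
    if (i == 1L && i == k) { left_ok <- endpoints; right_ok <- endpoints }
    if (left_ok && right_ok) {
      if (!positive_only || r$values[i] > 0)
        out <- c(out, (starts[i] + ends[i]) %/% 2L)
    }
  }
  out
}

# Deterministic RNG setup, pinned so fixture streams are stable across
# R versions and platforms.
#' @noRd
with_pinned_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}

# Write lines as a UTF-8 text file with "\n" endings, deterministically.
#' @noRd
write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
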