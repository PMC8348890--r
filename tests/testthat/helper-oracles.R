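# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most literal algorithm available, not the
# package's own code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Hamming distance between two equal-length strings.
hamming_dist <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Naive re-scan pentapeptide count: one window at a time.
oracle_count <- function(seqs) {
  out <- new.env(hash = TRUE)
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < 5) next
    for (i in seq_len(n - 4)) {
      w <- substr(s, i, i + 4)
      if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", w)) next
      prev <- if (exists(w, envir = out)) get(w, envir = out) else 0L
      assign(w, prev + 1L, envir = out)
    }
  }
  counts <- unlist(as.list(out))
  counts[order(names(counts), method = "radix")]
}

# Total frequency by scanning every key of the table (independent of ball
# enumeration).
oracle_phi <- function(table, fragment, delta) {
  keys <- names(table$counts)
  sel <- vapply(keys, hamming_dist, 1, b = fragment) <= delta
  sum(table$counts[sel])
}

# Literal double-loop convolution for the smoothed distribution.
oracle_smooth <- function(f, positions, x, y) {
  tot <- 0
  for (k in seq_along(positions)) {
    j <- positions[k]
    tot <- tot + f[k] * exp(-(x - j)^2 / (2 * y^2)) / (y * sqrt(2 * pi))
  }
  tot
}

# Log smoothed distribution one grid point at a time (log-sum-exp written
# out locally).
oracle_logF <- function(f, positions, n, y) {
  vapply(seq_len(n), function(z) {
    terms <- -((z - positions)^2) / (2 * y^2) +
      ifelse(f > 0, log(f), -Inf) - log(y * sqrt(2 * pi))
    mx <- max(terms)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(terms - mx)))
  }, numeric(1))
}

# Exhaustive inscribed-height minimization over every grid point z.
oracle_inscribed <- function(f, positions, n, x, y,
                             logF = oracle_logF(f, positions, n, y)) {
  z <- seq_len(n)
  exp(min(logF + (z - x)^2 / (2 * y^2)))
}

# Interior strict local maxima, simplest possible definition (no plateau
# handling; only used on generic float data where ties do not occur).
oracle_strict_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
}

# Merge structure tracker for impulse fixtures: number of strict maxima of
# the height row per level, computed straight from the matrix.
oracle_maxima_per_level <- function(field) {
  vapply(seq_along(field$y_levels), function(k)
    length(oracle_strict_maxima(field$H[k, ])), integer(1))
}

# Exhaustive greedy CSA partition: at each start, the block end is found by
# explicitly testing every candidate square with a double loop.
oracle_csa <- function(mask) {
  n <- nrow(mask)
  all_ones <- function(a, b) {
    for (i in a:b) for (j in a:b) if (mask[i, j] != 1L) return(FALSE)
    TRUE
  }
  starts <- integer(0); ends <- integer(0)
  a <- 1L
  while (a <= n) {
    b <- a
    for (cand in seq(a, n)) if (all_ones(a, cand)) b <- cand else break
    starts <- c(starts, a); ends <- c(ends, b)
    a <- b + 1L
  }
  data.frame(y_start = starts, y_end = ends)
}

# Textbook cosine of two vectors.
oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  num / sqrt(na * nb)
}

# Random spiky frequency profile for scale-space tests: Poisson background
# plus a few large spikes, which yields trees with several branch points.
random_profile <- function(n, spikes = 3, id = "rnd") {
  f <- as.numeric(rpois(n - 4, 3))
  at <- sample.int(n - 4, spikes)
  f[at] <- f[at] + runif(spikes, 50, 200)
  anis:::new_freq_profile(f, id = id, n = n)
}

# Random symmetric 0/1 mask with unit diagonal.
random_mask <- function(n, p = 0.4) {
  m <- matrix(as.integer(runif(n * n) < p), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1L
  m
}

# Recursively collect all nodes of an elis_tree.
tree_nodes <- function(tree) {
  out <- list()
  rec <- function(nd) {
    out[[length(out) + 1L]] <<- nd
    for (ch in nd$children) rec(ch)
  }
  for (r in tree$roots) rec(r)
  out
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
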