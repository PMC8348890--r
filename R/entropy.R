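#' Normalize one height-field level to a probability distribution
#'
#' Divides the row `H(., y)` by its total mass so that it sums to one over
#' the unit-spaced grid (the discrete form of a unit-integral
#' normalization); the largest element absorbs the residual rounding so
#' the sum is exactly 1 and no entry can be driven negative.
#'
#' @param field A `height_field`.
#' @param y A computed level with positive total mass.
#' @return Probability vector over `x = 1..N`.
#' @export
normalize_level <- function(field, y) {
  stopifnot(inherits(field, "height_field"))
  k <- match(y, field$y_levels)
  if (is.na(k)) stop("level y = ", y, " was not computed")
  row <- field$H[k, ]
  tot <- sum(row)
  if (tot <= 0) stop("level y = ", y, " has zero total mass")
  p <- row / tot
  imax <- which.max(p)
  p[imax] <- 1 - sum(p[-imax])
  p
}

#' Shannon entropy of a probability vector
#'
#' \eqn{S = -\sum_x p(x) \log p(x)} in natural units (nats), with the
#' convention \eqn{0 \log 0 = 0}.  For the uniform distribution over `n`
#' bins this equals `log n`, the model entropy of a partition into `n`
#' equal segments.
#'
#' @param p Non-negative numeric vector summing to 1 (within 1e-8).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0))
    stop("'p' must be a non-negative probability vector")
  if (abs(sum(p) - 1) > 1e-8)
    stop("'p' must sum to 1 (got ", format(sum(p)), ")")
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Entropy curves of a protein's hierarchy
#'
#' Per level `y`: the Shannon entropy `S(y)` of the normalized height row;
#' the number `n(y)` of ELIS branches alive at that level; the deviation
#' \eqn{\tilde S(y) = S(y) - \log n(y)} of the real entropy from the model
#' entropy of a uniform partition into `n` segments; and the forward
#' difference \eqn{S'(y) = \tilde S(y+1) - \tilde S(y)} (defined for
#' `y = 1 .. y_max - 1`), whose local maxima mark branch points of the
#' tree.  Levels with zero height mass are skipped with a warning and carry
#' `NA`.
#'
#' @param field A `height_field` and
#' @param tree the `elis_tree` extracted from it (same record and delta).
#' @param difference `"forward"` (default) or `"central"` finite difference
#'   for `S_prime`; the central form averages the two adjacent forward
#'   steps.
#' @return Object of class `entropy_curves`: list with `id`, `y_levels`,
#'   `S`, `n`, `S_dev`, `S_prime` (one fewer entry than `y_levels`, indexed
#'   by its lower level) and `y_prime` (those levels).
#' @export
entropy_curves <- function(field, tree, difference = c("forward", "central")) {
  stopifnot(inherits(field, "height_field"), inherits(tree, "elis_tree"))
  difference <- match.arg(difference)
  if (!identical(field$id, tree$id) || field$n != tree$n)
    stop("height field and tree come from different records")
  ylev <- field$y_levels
  S <- rep(NA_real_, length(ylev))
  nb <- rep(NA_integer_, length(ylev))
  for (k in seq_along(ylev)) {
    y <- ylev[k]
    tot <- sum(field$H[k, ])
    if (tot <= 0) {
      warning("level y = ", y, " has zero height mass; skipped")
      next
    }
    S[k] <- shannon_entropy(normalize_level(field, y))
    nb[k] <- nrow(elis_at_level(tree, y))
    if (nb[k] < 1L) nb[k] <- NA_integer_
  }
  S_dev <- S - log(nb)
  fd <- diff(S_dev)
  S_prime <- switch(difference,
                    forward = fd,
                    central = {
                      cp <- fd
                      if (length(fd) >= 2L)
                        cp[-1L] <- (fd[-1L] + fd[-length(fd)]) / 2
                      cp
                    })
  structure(list(id = field$id, y_levels = ylev, S = S, n = nb,
                 S_dev = S_dev, S_prime = S_prime,
                 y_prime = ylev[-length(ylev)],
                 difference = difference),
            class = "entropy_curves")
}

#' @noRd
new_entropy_curves <- function(S_prime, id = "synthetic") {
  y <- seq_len(length(S_prime) + 1L)
  S_dev <- c(0, cumsum(S_prime))
  structure(list(id = id, y_levels = y, S = S_dev, n = rep(1L, length(y)),
                 S_dev = S_dev, S_prime = as.numeric(S_prime),
                 y_prime = y[-length(y)], difference = "forward"),
            class = "entropy_curves")
}

#' @export
print.entropy_curves <- function(x, ...) {
  cat("Entropy curves of '", x$id, "' over levels ",
      min(x$y_levels), "..", max(x$y_levels), "\n", sep = "")
  bp <- branch_point_signal(x)
  if (length(bp))
    cat("  branch-point signal maxima at y =", paste(bp, collapse = ", "),
        "\n")
  invisible(x)
}

#' Branch-point levels from the entropy derivative
#'
#' The levels `y` at which `S_prime` attains a strict interior local
#' maximum (plateaus count once, at their midpoint).  These mark the
#' scales where the hierarchy branches: the entropy deviation jumps where
#' an ELIS of smaller rank emerges.
#'
#' @param curves An `entropy_curves` object.
#' @return Integer vector of levels (possibly empty).
#' @export
branch_point_signal <- function(curves) {
  stopifnot(inherits(curves, "entropy_curves"))
  sp <- curves$S_prime
  ok <- !is.na(sp)
  if (!all(ok)) sp <- sp[ok]
  idx <- local_maxima(sp, endpoints = FALSE, positive_only = FALSE)
  curves$y_prime[ok][idx]
}

#' Export entropy curves to TSV
#'
#' Columns `y`, `S`, `n`, `S_dev`, `S_prime` (empty on the last level),
#' preceded by `#` metadata lines.
#'
#' @param curves An `entropy_curves`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entropy_curves <- function(curves, path) {
  stopifnot(inherits(curves, "entropy_curves"))
  hdr <- c(paste0("# id: ", curves$id),
           paste0("# difference: ", curves$difference),
           "# columns: y\tS\tn\tS_dev\tS_prime")
  sp <- c(curves$S_prime, NA_real_)
  fmt <- function(v) ifelse(is.na(v), "NA",
                            formatC(v, format = "g", digits = 15))
  body <- paste(curves$y_levels, fmt(curves$S), curves$n,
                fmt(curves$S_dev), fmt(sp), sep = "\t")
  write_lines_utf8(c(hdr, body), path)
}
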