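#' Assemble per-level derivative vectors across a cohort
#'
#' For each hierarchy level `y`, collects into a vector `V_y` the
#' entropy-derivative values `S_prime(y)` of every protein whose triangle
#' reaches that level (a protein of length N contributes at
#' `y < floor(N/2)`), together with the membership telling which proteins
#' contribute where.  Levels reached by fewer than `min_proteins` proteins
#' are dropped.
#'
#' @param cohort Non-empty list of `entropy_curves` objects.
#' @param min_proteins Minimum cohort members per retained level.
#' @return Object of class `level_vectors`: list with `levels`, `values`
#'   (list of numeric vectors) and `members` (list of integer indices into
#'   `cohort`).
#' @export
build_level_vectors <- function(cohort, min_proteins = 10L) {
  if (!is.list(cohort) || length(cohort) == 0L ||
      !all(vapply(cohort, inherits, TRUE, "entropy_curves")))
    stop("'cohort' must be a non-empty list of entropy_curves")
  all_levels <- sort(unique(unlist(lapply(cohort, `[[`, "y_prime"))))
  values <- list(); members <- list(); levels <- integer(0)
  for (y in all_levels) {
    v <- numeric(0); m <- integer(0)
    for (i in seq_along(cohort)) {
      cu <- cohort[[i]]
      k <- match(y, cu$y_prime)
      if (!is.na(k) && !is.na(cu$S_prime[k])) {
        v <- c(v, cu$S_prime[k]); m <- c(m, i)
      }
    }
    if (length(m) >= min_proteins) {
      levels <- c(levels, y)
      values[[length(values) + 1L]] <- v
      members[[length(members) + 1L]] <- m
    }
  }
  if (length(levels) == 0L)
    stop("no level is shared by at least ", min_proteins, " proteins")
  structure(list(levels = levels, values = values, members = members,
                 n_proteins = length(cohort)),
            class = "level_vectors")
}

#' Cohort correlation matrix of derivative vectors
#'
#' The normalized inner product
#' \deqn{r_{yy'} = \frac{\langle V_y, V_{y'} \rangle}
#'   {\sqrt{\langle V_y, V_y \rangle \langle V_{y'}, V_{y'} \rangle}},
#'   \qquad \langle A, B \rangle = \sum_I A_I B_I,}
#' computed over the proteins shared by the two levels (pairwise-complete
#' intersection).  The diagonal is exactly 1 wherever `V_y` has positive
#' norm; all entries are bounded by 1 in magnitude (Cauchy--Schwarz).
#' Pairs sharing fewer than `min_pair` proteins, and rows with zero norm,
#' are set to `NA` and logged.
#'
#' @param vectors A `level_vectors` object.
#' @param min_pair Minimum shared proteins per matrix entry.
#' @return Object of class `cohort_matrix`: list with `levels`, `r`
#'   (symmetric matrix) and `pair_counts`.
#' @export
correlation_matrix <- function(vectors, min_pair = 10L) {
  stopifnot(inherits(vectors, "level_vectors"))
  L <- length(vectors$levels)
  r <- matrix(NA_real_, L, L,
              dimnames = list(vectors$levels, vectors$levels))
  pc <- matrix(0L, L, L, dimnames = dimnames(r))
  degenerate <- logical(L)
  for (a in seq_len(L)) {
    va <- vectors$values[[a]]
    degenerate[a] <- sum(va * va) == 0
    if (degenerate[a]) next
    r[a, a] <- 1
    pc[a, a] <- length(va)
  }
  if (any(degenerate))
    message("zero-norm level vector(s) at y = ",
            paste(vectors$levels[degenerate], collapse = ", "),
            "; corresponding rows masked")
  for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    if (degenerate[a] || degenerate[b]) next
    shared <- intersect(vectors$members[[a]], vectors$members[[b]])
    pc[a, b] <- pc[b, a] <- length(shared)
    if (length(shared) < min_pair) next
    va <- vectors$values[[a]][match(shared, vectors$members[[a]])]
    vb <- vectors$values[[b]][match(shared, vectors$members[[b]])]
    na <- sum(va * va); nb <- sum(vb * vb)
    if (na == 0 || nb == 0) next
    r[a, b] <- r[b, a] <- sum(va * vb) / sqrt(na * nb)
  }
  structure(list(levels = vectors$levels, r = r, pair_counts = pc),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("Cohort correlation matrix over ", length(x$levels), " levels (y = ",
      min(x$levels), "..", max(x$levels), ")\n", sep = "")
  off <- x$r[upper.tri(x$r)]
  if (any(!is.na(off)))
    cat("  off-diagonal range: ",
        format(min(off, na.rm = TRUE), digits = 4), " .. ",
        format(max(off, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Threshold a cohort matrix into a binary mask
#'
#' `mask(y, y') = 1` iff `r(y, y')` strictly exceeds `t`; undefined entries
#' count as 0; the diagonal is always 1.
#'
#' @param matrix A `cohort_matrix`.
#' @param t Threshold, strictly between 0 and 1.
#' @return Binary (0/1) integer matrix with the level dimnames.
#' @export
threshold_mask <- function(matrix, t) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t >= 1)
    stop("'t' must lie strictly between 0 and 1")
  m <- (matrix$r > t)
  m[is.na(m)] <- FALSE
  diag(m) <- TRUE
  storage.mode(m) <- "integer"
  m
}

#' Detect continuous square areas along the diagonal
#'
#' Partitions the diagonal of a thresholded mask, left to right, into
#' maximal intervals `[a, b]` such that every matrix element with both
#' indices in `[a, b]` is 1 and no further extension preserves this;
#' singletons are allowed (the diagonal itself is always 1).
#'
#' @param mask Square symmetric 0/1 matrix with unit diagonal, as from
#'   [threshold_mask()].
#' @param levels Optional level labels for the rows (defaults to the
#'   dimnames, or `1..nrow`).
#' @return A `data.frame` with columns `y_start`, `y_end` (inclusive level
#'   range), ordered and disjoint.
#' @export
detect_csa <- function(mask, levels = NULL) {
  if (!is.matrix(mask) || nrow(mask) != ncol(mask))
    stop("'mask' must be a square matrix")
  if (!isTRUE(all(mask == t(mask))))
    stop("'mask' must be symmetric")
  if (!all(diag(mask) == 1)) stop("'mask' must have a unit diagonal")
  n <- nrow(mask)
  if (is.null(levels)) {
    levels <- if (!is.null(rownames(mask))) as.integer(rownames(mask))
              else seq_len(n)
  }
  starts <- integer(0); ends <- integer(0)
  a <- 1L
  while (a <= n) {
    b <- a
    while (b < n && all(mask[a:(b + 1L), b + 1L] == 1L)) b <- b + 1L
    starts <- c(starts, a); ends <- c(ends, b)
    a <- b + 1L
  }
  data.frame(y_start = levels[starts], y_end = levels[ends])
}

#' Scan decreasing thresholds for a stable CSA structure
#'
#' Runs [detect_csa()] at each threshold of a strictly decreasing schedule
#' and returns the first block set that is identical for two consecutive
#' thresholds -- the point at which lowering the threshold no longer
#' changes the diagonal block structure -- together with the threshold at
#' which stability is first reached.  If the structure never repeats, the
#' final block set is returned flagged unstable.
#'
#' @param matrix A `cohort_matrix`.
#' @param thresholds Strictly decreasing values in (0, 1), length >= 2.
#'   The default schedule spans 0.9 down to 0.001.
#' @return Object of class `csa_result`: list with `blocks` (data frame as
#'   from [detect_csa()]), `threshold` (stabilization threshold, `NA` if
#'   unstable), `stable` (logical) and `per_threshold` (list of block sets).
#' @export
stability_scan <- function(matrix,
                           thresholds = c(0.9, 0.7, 0.5, 0.3, 0.1,
                                          0.05, 0.02, 0.01, 0.001)) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  if (length(thresholds) < 2L) stop("'thresholds' must have length >= 2")
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("'thresholds' must lie strictly between 0 and 1")
  if (any(diff(thresholds) >= 0))
    stop("'thresholds' must be strictly decreasing")
  sets <- lapply(thresholds, function(t)
    detect_csa(threshold_mask(matrix, t), levels = matrix$levels))
  for (i in seq_len(length(sets) - 1L)) {
    if (identical(sets[[i]], sets[[i + 1L]])) {
      return(structure(list(blocks = sets[[i]], threshold = thresholds[i],
                            stable = TRUE, thresholds = thresholds,
                            per_threshold = sets),
                       class = "csa_result"))
    }
  }
  structure(list(blocks = sets[[length(sets)]], threshold = NA_real_,
                 stable = FALSE, thresholds = thresholds,
                 per_threshold = sets),
            class = "csa_result")
}

#' @export
print.csa_result <- function(x, ...) {
  if (x$stable) {
    cat("CSA structure stable from threshold ", format(x$threshold),
        ": ", nrow(x$blocks), " diagonal block(s)\n", sep = "")
  } else {
    cat("CSA structure did not stabilize over the schedule; final set has ",
        nrow(x$blocks), " block(s)\n", sep = "")
  }
  wide <- x$blocks[x$blocks$y_end > x$blocks$y_start, , drop = FALSE]
  if (nrow(wide)) {
    cat("  multi-level blocks:\n")
    for (i in seq_len(nrow(wide)))
      cat("    y = ", wide$y_start[i], "-", wide$y_end[i], "\n", sep = "")
  }
  invisible(x)
}

#' Export a cohort matrix (TSV with level headers)
#'
#' @param matrix A `cohort_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  fmt <- function(v) ifelse(is.na(v), "NA",
                            formatC(v, format = "g", digits = 15))
  hdr <- paste(c("y", matrix$levels), collapse = "\t")
  body <- vapply(seq_along(matrix$levels), function(a)
    paste(c(matrix$levels[a], fmt(matrix$r[a, ])), collapse = "\t"), "")
  write_lines_utf8(c(hdr, body), path)
}

#' Export a binary mask as 0/1 TSV
#'
#' @param mask Matrix from [threshold_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  hdr <- paste(c("y", rownames(mask)), collapse = "\t")
  body <- vapply(seq_len(nrow(mask)), function(a)
    paste(c(rownames(mask)[a], mask[a, ]), collapse = "\t"), "")
  write_lines_utf8(c(hdr, body), path)
}

#' Export CSA blocks as TSV
#'
#' Columns `y_start`, `y_end`, `stable_threshold`.
#'
#' @param result A `csa_result` from [stability_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csa <- function(result, path) {
  stopifnot(inherits(result, "csa_result"))
  thr <- if (is.na(result$threshold)) "unstable" else
    formatC(result$threshold, format = "g", digits = 15)
  body <- paste(result$blocks$y_start, result$blocks$y_end, thr, sep = "\t")
  write_lines_utf8(c("y_start\ty_end\tstable_threshold", body), path)
}
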