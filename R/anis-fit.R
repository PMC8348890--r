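#' Fit the hierarchical informational structure of one protein
#'
#' The central per-protein analysis: computes the total-frequency profile
#' of the sequence against a pentapeptide database table, the inscribed
#' Gaussian height field over the triangular scale-space domain, the ELIS
#' hierarchy tree of its level-wise local maxima, and the entropy curves
#' whose derivative maxima mark the branch points.
#'
#' @param record One sequence: a (optionally named) character string or a
#'   one-row records `data.frame`.
#' @param table A `penta_table` built over a non-redundant collection.
#' @param delta Hamming radius for the total frequency (default 1).
#' @param difference Finite-difference scheme for the entropy derivative.
#' @return Object of class `anis`: list with components `profile`
#'   (`freq_profile`), `field` (`height_field`), `tree` (`elis_tree`),
#'   `curves` (`entropy_curves`) and `branch_levels` (the entropy-detected
#'   branch levels).
#' @seealso [csa_scan()] for the cohort-level analysis.
#' @export
anis <- function(record, table, delta = 1L,
                 difference = c("forward", "central")) {
  difference <- match.arg(difference)
  profile <- frequency_profile(record, table, delta = delta)
  fit_anis_profile(profile, difference = difference)
}

# Shared tail of the fit, also used when the profile is synthetic.
#' @noRd
fit_anis_profile <- function(profile, difference = "forward") {
  field <- height_field(profile)
  tree <- build_elis_tree(field)
  curves <- entropy_curves(field, tree, difference = difference)
  structure(list(profile = profile, field = field, tree = tree,
                 curves = curves,
                 branch_levels = branch_point_signal(curves)),
            class = "anis")
}

#' @export
print.anis <- function(x, ...) {
  cat("ANIS decomposition of '", x$profile$id, "' (N = ", x$profile$n,
      ", delta = ", x$profile$delta, ")\n", sep = "")
  print(x$tree)
  if (length(x$branch_levels))
    cat("entropy branch signal at y =",
        paste(x$branch_levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.anis <- function(object, levels = NULL, ...) {
  if (is.null(levels)) {
    ymax <- object$tree$y_max
    levels <- unique(pmax(1L, c(1L, ymax %/% 4L, ymax %/% 2L, ymax)))
  }
  segs <- lapply(levels, function(y) elis_at_level(object$tree, y))
  out <- list(id = object$profile$id, n = object$profile$n,
              levels = levels, segments = segs,
              branch_levels = object$branch_levels)
  class(out) <- "summary.anis"
  out
}

#' @export
print.summary.anis <- function(x, ...) {
  cat("ELIS segments of '", x$id, "' (N = ", x$n, ")\n", sep = "")
  for (k in seq_along(x$levels)) {
    s <- x$segments[[k]]
    cat("  y = ", format(x$levels[k], width = 3), ": ",
        paste(sprintf("%d-%d", s$start, s$end), collapse = "  "),
        "\n", sep = "")
  }
  if (length(x$branch_levels))
    cat("branch signal at y =", paste(x$branch_levels, collapse = ", "),
        "\n")
  invisible(x)
}

#' Plot an ANIS decomposition
#'
#' Draws the inscribed-height field over the triangular `(x, y)` domain as
#' an image, with the tracked ELIS branch traces overlaid, and marks the
#' branch points.
#'
#' @param x An `anis` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.anis <- function(x, ...) {
  f <- x$field
  graphics::image(x = seq_len(f$n), y = f$y_levels, z = t(f$H),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue position x", ylab = "scale y",
                  main = paste0("ANIS: ", f$id), ...)
  tree_walk(x$tree, function(nd) {
    graphics::lines(nd$trace$x, nd$trace$y, lwd = 1.5)
    if (!is.null(nd$branch_point))
      graphics::points(nd$branch_point["x0"], nd$branch_point["y0"],
                       pch = 19, cex = 0.7, col = "blue")
  })
  invisible(x)
}

#' Cohort-level characteristic-scale analysis
#'
#' Assembles the per-level entropy-derivative vectors of a protein cohort,
#' computes the cosine-normalized correlation matrix, and scans a
#' decreasing threshold schedule for a stable continuous-square-area (CSA)
#' structure along the diagonal.  The stable diagonal blocks are the
#' cohort's characteristic hierarchy scales.
#'
#' @param cohort List of `entropy_curves` (or `anis`) objects.
#' @param thresholds Strictly decreasing threshold schedule in (0, 1).
#' @param min_proteins Minimum proteins per retained level.
#' @param min_pair Minimum shared proteins per matrix entry.
#' @return Object of class `anis_csa`: list with `vectors`, `matrix`
#'   (`cohort_matrix`) and `result` (`csa_result`).
#' @export
csa_scan <- function(cohort,
                     thresholds = c(0.9, 0.7, 0.5, 0.3, 0.1,
                                    0.05, 0.02, 0.01, 0.001),
                     min_proteins = 10L, min_pair = 10L) {
  cohort <- lapply(cohort, function(el)
    if (inherits(el, "anis")) el$curves else el)
  vectors <- build_level_vectors(cohort, min_proteins = min_proteins)
  mat <- correlation_matrix(vectors, min_pair = min_pair)
  res <- stability_scan(mat, thresholds = thresholds)
  structure(list(vectors = vectors, matrix = mat, result = res),
            class = "anis_csa")
}

#' @export
print.anis_csa <- function(x, ...) {
  cat("Cohort of ", x$vectors$n_proteins, " proteins, levels y = ",
      min(x$vectors$levels), "..", max(x$vectors$levels), "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Plot the thresholded cohort matrix with its CSA blocks
#'
#' @param x An `anis_csa` object.
#' @param t Threshold for the displayed mask; defaults to the stabilization
#'   threshold (or the last of the schedule when unstable).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.anis_csa <- function(x, t = NULL, ...) {
  if (is.null(t))
    t <- if (x$result$stable) x$result$threshold
         else min(x$result$thresholds)
  m <- threshold_mask(x$matrix, t)
  lv <- x$matrix$levels
  graphics::image(x = lv, y = lv, z = m,
                  col = c("white", "grey40"),
                  xlab = "y", ylab = "y'",
                  main = sprintf("r > %g", t), ...)
  blk <- x$result$blocks
  for (i in seq_len(nrow(blk)))
    graphics::rect(blk$y_start[i] - 0.5, blk$y_start[i] - 0.5,
                   blk$y_end[i] + 0.5, blk$y_end[i] + 0.5,
                   border = "red", lwd = 2)
  invisible(x)
}
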