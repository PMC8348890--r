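#' Inscribed Gaussian height at one scale-space point
#'
#' The largest amplitude `h` such that the Gaussian `h * exp(-(z-x)^2/(2y^2))`
#' of half-width `y` centred at `x` fits entirely under the smoothed profile
#' `F`:
#' \deqn{H_I(x, y) = \min_z F_I(z)\, e^{(z-x)^2/(2y^2)}}
#' with `z` ranging over the integer grid `1..N`.  The product is evaluated
#' in the log domain so that far-away grid points, where the exponential
#' factor is astronomically large but `F` is astronomically small, are
#' handled without overflow or underflow.
#'
#' @param F A `smoothed_profile` computed at the same scale `y`, or a plain
#'   non-negative numeric vector giving `F` on the grid.
#' @param x Grid position in `1..N`.
#' @param y Positive scale (must match `F$y` when `F` is a profile object).
#' @return The inscribed amplitude, a non-negative number; 0 when `F` is
#'   zero anywhere (an all-zero `F` included), and never larger than `F(x)`.
#' @export
inscribed_height <- function(F, x, y) {
  if (inherits(F, "smoothed_profile")) {
    if (!isTRUE(all.equal(F$y, y)))
      stop("'F' was computed at scale y = ", F$y, ", not ", y)
    logF <- F$log_values
  } else {
    F <- as.numeric(F)
    if (any(F < 0)) stop("'F' must be non-negative")
    logF <- ifelse(F > 0, log(F), -Inf)
  }
  n <- length(logF)
  if (!is_count(x) || x < 1 || x > n) stop("'x' must lie in 1..", n)
  if (!is.numeric(y) || length(y) != 1L || y <= 0)
    stop("'y' must be a single positive number")
  z <- seq_len(n)
  exp(min(logF + (z - x)^2 / (2 * y^2)))
}

#' Inscribed-height field over the triangular scale-space domain
#'
#' For each integer scale `y` in `y_levels` the smoothed distribution `F` is
#' recomputed with kernel half-width `y`, and the inscribed height is
#' evaluated at every grid position `x = 1..N`.  The natural domain is the
#' isosceles triangle with base `x` in `[1, N]` and height `y` in
#' `[1, N/2]`; the default levels are the integers `1..floor(N/2)`.
#'
#' @param profile A `freq_profile` (N >= 5).
#' @param y_levels Integer scales, a subset of `1..floor(N/2)`; default all.
#' @return Object of class `height_field`: list with `id`, `n`, `delta`,
#'   `y_levels`, `H` (matrix, rows = levels, columns = x) and `F` (the
#'   matching smoothed values, same shape).
#' @export
height_field <- function(profile, y_levels = NULL) {
  stopifnot(inherits(profile, "freq_profile"))
  n <- profile$n
  if (n < 5L) stop("sequence too short (N = ", n, ")")
  ymax <- n %/% 2L
  if (is.null(y_levels)) y_levels <- seq_len(ymax)
  y_levels <- as.integer(y_levels)
  if (any(y_levels < 1L | y_levels > ymax))
    stop("'y_levels' must lie in 1..", ymax)
  x <- seq_len(n)
  H <- matrix(0, nrow = length(y_levels), ncol = n,
              dimnames = list(y = y_levels, x = x))
  Fm <- H
  SQ <- outer(x, x, "-")^2
  for (k in seq_along(y_levels)) {
    y <- y_levels[k]
    D <- SQ / (2 * y^2)
    logF <- smooth_log_core(D[, profile$positions, drop = FALSE],
                            profile$values, y)
    B <- logF + D                      # B[z, x]; logF recycles down columns
    H[k, ] <- exp(col_mins(B))
    Fm[k, ] <- exp(logF)
  }
  structure(list(id = profile$id, n = n, delta = profile$delta,
                 y_levels = y_levels, H = H, F = Fm),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat("Inscribed-height field of '", x$id, "': N = ", x$n, ", levels y = ",
      min(x$y_levels), "..", max(x$y_levels), "\n", sep = "")
  invisible(x)
}

#' Level-wise local maxima of the height field
#'
#' Positions of strict local maxima of `H(., y)` at a fixed level.  A run of
#' equal values flanked by strictly smaller values counts as one maximum at
#' its midpoint (rounded down); a domain endpoint qualifies when strictly
#' above its single neighbour.  Maxima of height zero are not reported.
#'
#' @param field A `height_field`.
#' @param y A computed level.
#' @return Increasing integer positions.
#' @export
level_maxima <- function(field, y) {
  stopifnot(inherits(field, "height_field"))
  k <- match(y, field$y_levels)
  if (is.na(k)) stop("level y = ", y, " was not computed")
  unname(local_maxima(field$H[k, ], endpoints = TRUE, positive_only = TRUE))
}

#' @noRd
basin_bounds <- function(maxima, pos, n) {
  i <- match(pos, maxima)
  left <- if (i == 1L) 1L else (maxima[i - 1L] + maxima[i]) %/% 2L + 1L
  right <- if (i == length(maxima)) n else (maxima[i] + maxima[i + 1L]) %/% 2L
  c(left, right)
}

#' Extract the ELIS hierarchy tree from a height field
#'
#' Scans the levels from the top of the triangle downward, tracking each
#' local maximum of `H(., y)` as a branch: every maximum at level `y - 1`
#' is assigned to the nearest tracked maximum at level `y` (ties broken to
#' the left).  A branch whose basin acquires two or more maxima at the
#' level below splits there: it records a branch point `(x0, y0)` -- its
#' own position at the last level where the sub-branches are still merged
#' -- and its children become branches of the next rank.  Branch intervals
#' are basin boundaries: a root takes its midpoint basin at the top level
#' (domain ends at the flanks), and a split partitions the parent interval
#' at the midpoints between the children's positions at the split level.
#' Evaluating each partition at the level where the branches emerge keeps
#' the hierarchy exactly nested and the intervals alive at any level
#' pairwise disjoint even when tracked maxima drift across levels.
#'
#' @param field A `height_field` covering the contiguous levels
#'   `1..floor(N/2)`.
#' @return Object of class `elis_tree`: list with `roots` (ordered list of
#'   nodes, each with `interval`, `y_birth`, `y_death`, `branch_point`,
#'   `rank`, `children` and a position `trace`), `n`, `y_max`, `id`,
#'   `delta`.  An all-zero field yields an empty forest with a warning.
#' @export
build_elis_tree <- function(field) {
  stopifnot(inherits(field, "height_field"))
  ymax <- field$n %/% 2L
  if (!identical(field$y_levels, seq_len(ymax)))
    stop("tree extraction needs the contiguous levels 1..", ymax)
  n <- field$n
  maxima <- lapply(seq_len(ymax), function(y) level_maxima(field, y))

  nodes <- list()    # growing store of node records
  new_node <- function(parent, y_birth, pos) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, children = integer(0),
                         y_birth = y_birth, y_death = NA_integer_,
                         branch_point = NULL,
                         trace_y = y_birth, trace_x = pos)
    id
  }
  if (length(maxima[[ymax]]) == 0L) {
    has_any <- any(vapply(maxima, length, 1L) > 0L)
    if (!has_any) {
      warning("height field has no local maxima; empty forest")
      return(structure(list(roots = list(), n = n, y_max = ymax,
                            id = field$id, delta = field$delta),
                       class = "elis_tree"))
    }
  }
  active <- integer(0)
  active_pos <- integer(0)
  for (p in maxima[[ymax]]) {
    active <- c(active, new_node(NA_integer_, ymax, p))
    active_pos <- c(active_pos, p)
  }
  for (y in rev(seq_len(ymax - 1L))) {
    m <- maxima[[y]]
    if (length(active) == 0L) {
      # branches vanished higher up; any new maxima start fresh roots
      for (p in m) {
        active <- c(active, new_node(NA_integer_, y, p))
        active_pos <- c(active_pos, p)
      }
      next
    }
    if (length(m) == 0L) {
      for (id in active) nodes[[id]]$y_death <- y + 1L
      active <- integer(0); active_pos <- integer(0)
      next
    }
    # nearest active maximum; which.min takes the first (leftmost) on ties
    assignment <- vapply(m, function(p) which.min(abs(active_pos - p)), 1L)
    next_active <- integer(0); next_pos <- integer(0)
    for (k in seq_along(active)) {
      kids <- m[assignment == k]
      id <- active[k]
      if (length(kids) == 1L) {
        nodes[[id]]$trace_y <- c(nodes[[id]]$trace_y, y)
        nodes[[id]]$trace_x <- c(nodes[[id]]$trace_x, kids)
        next_active <- c(next_active, id); next_pos <- c(next_pos, kids)
      } else if (length(kids) >= 2L) {
        nodes[[id]]$y_death <- y + 1L
        nodes[[id]]$branch_point <- c(x0 = unname(active_pos[k]),
                                      y0 = y + 1L)
        for (p in kids) {
          cid <- new_node(id, y, p)
          nodes[[id]]$children <- c(nodes[[id]]$children, cid)
          next_active <- c(next_active, cid); next_pos <- c(next_pos, p)
        }
      } else {
        nodes[[id]]$y_death <- y + 1L   # vanished: leaf ending above level 1
      }
    }
    ord <- order(next_pos)
    active <- next_active[ord]; active_pos <- next_pos[ord]
  }
  for (id in active) nodes[[id]]$y_death <- 1L

  # a subtree ultimately needs one grid position per leaf branch
  need <- function(id) {
    ch <- nodes[[id]]$children
    if (length(ch) == 0L) 1L else sum(vapply(ch, need, 1L))
  }

  # Partition [iv[1], iv[2]] into k contiguous non-empty slots anchored at
  # the midpoints between the children's positions at the split level;
  # each slot is widened where necessary to hold its subtree's leaves
  # (tracked maxima can drift across boundaries fixed higher up).
  slot_cuts <- function(iv, pos, needs) {
    k <- length(pos)
    q <- pmin(pmax(pos, iv[1]), iv[2])
    cuts <- (q[-k] + q[-1L]) %/% 2L
    lo <- iv[1] - 1L
    for (i in seq_len(k - 1L))
      cuts[i] <- max(cuts[i], lo + sum(needs[1:i]))
    for (i in rev(seq_len(k - 1L)))
      cuts[i] <- min(cuts[i],
                     iv[2] - sum(needs[(i + 1L):k]),
                     if (i < k - 1L) cuts[i + 1L] - 1L else iv[2] - 1L)
    if (k > 1L && (cuts[1] < iv[1] || any(diff(cuts) < 1L))) {
      # no anchored partition can hold every subtree: spread evenly
      cuts <- lo + round(cumsum(needs[-k]) / sum(needs) *
                           (iv[2] - lo))
      cuts <- pmin(pmax(cuts, lo + seq_len(k - 1L)),
                   iv[2] - rev(seq_len(k - 1L)))
    }
    cuts
  }

  assemble <- function(id, iv, rank) {
    nd <- nodes[[id]]
    kids <- list()
    if (length(nd$children)) {
      birth_pos <- vapply(nd$children, function(cid)
        nodes[[cid]]$trace_x[1], 1L)
      ord <- order(birth_pos)
      cids <- nd$children[ord]
      needs <- vapply(cids, need, 1L)
      cuts <- slot_cuts(iv, birth_pos[ord], needs)
      lo <- c(iv[1], cuts + 1L)
      hi <- c(cuts, iv[2])
      kids <- lapply(seq_along(cids), function(i)
        assemble(cids[i], iv = c(lo[i], hi[i]), rank = rank + 1L))
    }
    list(interval = iv, y_birth = nd$y_birth, y_death = nd$y_death,
         branch_point = nd$branch_point, rank = rank, children = kids,
         trace = data.frame(y = nd$trace_y, x = nd$trace_x))
  }
  root_ids <- which(vapply(nodes, function(nd) is.na(nd$parent), TRUE))
  root_birth <- vapply(root_ids, function(id) nodes[[id]]$y_birth, 1L)
  root_pos <- vapply(root_ids, function(id) nodes[[id]]$trace_x[1], 1L)
  roots <- list()
  for (b in sort(unique(root_birth), decreasing = TRUE)) {
    sel <- which(root_birth == b)
    sel <- sel[order(root_pos[sel])]
    ids <- root_ids[sel]
    needs <- vapply(ids, need, 1L)
    cuts <- if (length(ids) > 1L)
      slot_cuts(c(1L, n), root_pos[sel], needs) else integer(0)
    lo <- c(1L, cuts + 1L)
    hi <- c(cuts, n)
    for (i in seq_along(ids))
      roots[[length(roots) + 1L]] <-
        assemble(ids[i], iv = c(lo[i], hi[i]), rank = 1L)
  }
  ord <- order(vapply(roots, function(r) r$interval[1], 1L))
  roots <- roots[ord]
  structure(list(roots = roots, n = n, y_max = ymax,
                 id = field$id, delta = field$delta),
            class = "elis_tree")
}

#' @noRd
tree_walk <- function(tree, fn) {
  rec <- function(node) {
    fn(node)
    lapply(node$children, rec)
    invisible(NULL)
  }
  lapply(tree$roots, rec)
  invisible(NULL)
}

#' @export
print.elis_tree <- function(x, ...) {
  n_nodes <- 0L; n_bp <- 0L; max_rank <- 0L
  tree_walk(x, function(nd) {
    n_nodes <<- n_nodes + 1L
    if (!is.null(nd$branch_point)) n_bp <<- n_bp + 1L
    max_rank <<- max(max_rank, nd$rank)
  })
  cat("ELIS tree of '", x$id, "' (N = ", x$n, "): ",
      length(x$roots), " root(s), ", n_nodes, " branches, ",
      n_bp, " branch points, max rank ", max_rank, "\n", sep = "")
  invisible(x)
}

#' ELIS intervals alive at a hierarchy level
#'
#' Returns the sequence intervals of all branches that exist at scale `y`
#' (branches whose level range `[y_death, y_birth]` contains `y`), disjoint
#' and ordered by start position.
#'
#' @param tree An `elis_tree`.
#' @param y Level in `1..floor(N/2)`.
#' @return A `data.frame` with columns `start`, `end`, `rank`.
#' @export
elis_at_level <- function(tree, y) {
  stopifnot(inherits(tree, "elis_tree"))
  if (!is_count(y) || y < 1 || y > tree$y_max)
    stop("'y' must lie in 1..", tree$y_max)
  starts <- integer(0); ends <- integer(0); ranks <- integer(0)
  tree_walk(tree, function(nd) {
    if (nd$y_death <= y && y <= nd$y_birth) {
      starts <<- c(starts, nd$interval[1])
      ends <<- c(ends, nd$interval[2])
      ranks <<- c(ranks, nd$rank)
    }
  })
  ord <- order(starts)
  data.frame(start = starts[ord], end = ends[ord], rank = ranks[ord])
}

#' Export a height field as a TSV matrix
#'
#' Rows are levels `y` (first column), columns the grid positions `x`, with
#' a `#` metadata header.
#'
#' @param field A `height_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_height_field <- function(field, path) {
  stopifnot(inherits(field, "height_field"))
  hdr <- c(paste0("# id: ", field$id),
           paste0("# n: ", field$n),
           paste0("# delta: ", field$delta),
           paste0("# columns: y\tx1..x", field$n))
  body <- vapply(seq_along(field$y_levels), function(k) {
    paste(c(field$y_levels[k],
            formatC(field$H[k, ], format = "g", digits = 15)),
          collapse = "\t")
  }, "")
  write_lines_utf8(c(hdr, body), path)
}

#' @noRd
node_to_list <- function(nd) {
  list(interval = nd$interval, y_birth = nd$y_birth, y_death = nd$y_death,
       branch_point = if (is.null(nd$branch_point)) NULL else
         list(x0 = unname(nd$branch_point[1]),
              y0 = unname(nd$branch_point[2])),
       rank = nd$rank,
       children = lapply(nd$children, node_to_list))
}

#' Export an ELIS tree as JSON
#'
#' Nodes carry `interval`, `y_birth`, `y_death`, `branch_point` (absent for
#' unsplit branches), `rank` and nested `children`.
#'
#' @param tree An `elis_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elis_tree <- function(tree, path) {
  stopifnot(inherits(tree, "elis_tree"))
  obj <- list(id = tree$id, n = tree$n, y_max = tree$y_max,
              delta = tree$delta,
              roots = lapply(tree$roots, node_to_list))
  write_lines_utf8(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                    digits = NA, pretty = TRUE),
                   path)
}

#' Newick-style rendering of an ELIS tree
#'
#' Each branch is labelled `start-end` with branch length equal to the
#' number of levels it spans; a forest is wrapped in a virtual root
#' spanning the whole sequence.  Intended for quick viewing in standard
#' tree viewers.
#'
#' @param tree An `elis_tree`.
#' @return A single Newick string.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "elis_tree"))
  rec <- function(nd) {
    lab <- paste0(nd$interval[1], "-", nd$interval[2])
    len <- nd$y_birth - nd$y_death + 1L
    if (length(nd$children) == 0L) return(paste0(lab, ":", len))
    paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")",
           lab, ":", len)
  }
  if (length(tree$roots) == 0L) return(";")
  if (length(tree$roots) == 1L) return(paste0(rec(tree$roots[[1]]), ";"))
  paste0("(", paste(vapply(tree$roots, rec, ""), collapse = ","), ")1-",
         tree$n, ";")
}
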