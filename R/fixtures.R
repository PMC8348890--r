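# Synthetic-data generators with planted, generation-time-verified
# structure.  These emulate the statistical shape of a non-redundant
# protein collection -- i.i.d. residues with an optional composition bias
# and optional over-represented pentapeptide motifs -- not real evolution:
# there are no residue correlations, no homology, and no secondary-
# structure signal.  What they do give is a known ground truth for every
# pipeline stage.

#' Generate a random protein database with optional planted motifs
#'
#' Draws `n_sequences` i.i.d. residue sequences with lengths uniform on
#' `length_range`, optionally overwrites random in-sequence windows with a
#' planted pentapeptide motif to inflate its occurrence count, and returns
#' both the records and their pentapeptide table.  Fully deterministic
#' under a fixed seed (pinned Mersenne-Twister stream).
#'
#' @param n_sequences Number of sequences (0 allowed).
#' @param length_range Integer `(min, max)` for uniform lengths; default
#'   the 50--400 residue window used for frequency databases.
#' @param seed Integer seed.
#' @param composition Optional length-20 non-negative weight vector over
#'   the alphabet (default uniform).
#' @param planted Optional list of `list(motif = <pentapeptide>,
#'   copies = <integer>)` entries; each copy overwrites a random window of
#'   a random sequence of length >= 5.
#' @return List with `records` (data.frame as from [scan_database()]) and
#'   `table` (their `penta_table`).
#' @export
random_database <- function(n_sequences, length_range = c(50L, 400L),
                            seed = 1L, composition = NULL, planted = NULL) {
  if (!is_count(n_sequences) || n_sequences < 0)
    stop("'n_sequences' must be a non-negative integer")
  if (length(length_range) != 2L || length_range[1] < 5L ||
      length_range[1] > length_range[2])
    stop("'length_range' must be (min, max) with 5 <= min <= max")
  if (!is.null(composition) &&
      (length(composition) != 20L || any(composition < 0) ||
       sum(composition) <= 0))
    stop("'composition' must be 20 non-negative weights")
  records <- with_pinned_seed(seed, {
    lens <- if (n_sequences > 0)
      sample(length_range[1]:length_range[2], n_sequences, replace = TRUE)
    else integer(0)
    seqs <- vapply(lens, function(n)
      paste(sample(AA_ALPHABET, n, replace = TRUE,
                   prob = composition), collapse = ""), "")
    if (!is.null(planted) && n_sequences > 0) {
      for (pl in planted) {
        motif <- toupper(pl$motif)
        if (nchar(motif) != 5L) stop("planted motif must have 5 residues")
        for (cp in seq_len(pl$copies)) {
          i <- sample.int(n_sequences, 1L)
          pos <- sample.int(lens[i] - 4L, 1L)
          substr(seqs[i], pos, pos + 4L) <- motif
        }
      }
    }
    data.frame(id = sprintf("syn%05d", seq_len(n_sequences)),
               residues = seqs, length = lens, stringsAsFactors = FALSE)
  })
  list(records = records, table = count_pentapeptides(records))
}

#' Write synthetic records as FASTA
#'
#' @param records A records `data.frame` (columns `id`, `residues`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(records$residues,
                                                records$id))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Construct a frequency profile with planted structure
#'
#' Three kinds of synthetic profile drive the scale-space tests:
#' * `impulse`: a single nonzero value `f(j0) = c`.  Its inscribed height
#'   obeys the closed form `H(j0, y) = c / (y * sqrt(2*pi))` at every
#'   scale, and its ELIS tree is a single branch.
#' * `two_impulse`: nonzero at `j1 < j2`; the tree has exactly one branch
#'   point whose level grows with the separation.
#' * `multi_scale`: two pairs of impulses arranged so the tree branches in
#'   two prescribed, well-separated level bands (pair spacing sets the low
#'   band, pair-to-pair spacing the high band).  The construction is
#'   verified at generation time by building the tree and checking every
#'   branch-point level falls in a band; failure is an error, so a
#'   returned profile certifies its own structure.
#'
#' @param kind `"impulse"`, `"two_impulse"` or `"multi_scale"`.
#' @param n Sequence length N (grid size).
#' @param j0,c Impulse position (central residue in `3..N-2`) and height.
#' @param j1,j2 Positions for `two_impulse` (must satisfy `j1 < j2`).
#' @param bands For `multi_scale`: list of two disjoint increasing integer
#'   ranges of levels, low band first, e.g. `list(3:6, 15:20)`.
#' @return A `freq_profile`; for `multi_scale` the verified branch-point
#'   levels are attached as attribute `branch_levels`.
#' @export
planted_profile <- function(kind = c("impulse", "two_impulse", "multi_scale"),
                            n = 100L, j0 = n %/% 2L, c = 100,
                            j1 = NULL, j2 = NULL, bands = NULL) {
  kind <- match.arg(kind)
  if (c <= 0) stop("'c' must be positive")
  f <- numeric(n - 4L)
  pos_index <- function(j) {
    if (j < 3L || j > n - 2L) stop("position ", j, " outside 3..", n - 2L)
    j - 2L
  }
  if (kind == "impulse") {
    f[pos_index(j0)] <- c
    return(new_freq_profile(f, id = "impulse", n = n))
  }
  if (kind == "two_impulse") {
    if (is.null(j1) || is.null(j2) || j2 <= j1)
      stop("'two_impulse' needs j1 < j2")
    f[pos_index(j1)] <- c
    f[pos_index(j2)] <- c
    return(new_freq_profile(f, id = "two_impulse", n = n))
  }
  # multi_scale
  if (!is.list(bands) || length(bands) != 2L)
    stop("'multi_scale' needs a list of two level bands")
  b1 <- as.integer(bands[[1]]); b2 <- as.integer(bands[[2]])
  if (max(b1) >= min(b2)) stop("bands must be disjoint, low band first")
  d_low <- 2L * as.integer(round(mean(b1)))
  d_high <- 2L * as.integer(round(mean(b2)))
  centre <- n %/% 2L
  pos <- c(centre - d_high %/% 2L - d_low %/% 2L,
           centre - d_high %/% 2L + d_low %/% 2L,
           centre + d_high %/% 2L - d_low %/% 2L,
           centre + d_high %/% 2L + d_low %/% 2L)
  if (pos[1] < 3L || pos[4] > n - 2L)
    stop("bands too wide for sequence length ", n)
  f[pos - 2L] <- c
  prof <- new_freq_profile(f, id = "multi_scale", n = n)
  tree <- build_elis_tree(height_field(prof))
  bp <- integer(0)
  tree_walk(tree, function(nd) {
    if (!is.null(nd$branch_point))
      bp <<- c(bp, unname(nd$branch_point["y0"]))
  })
  in_band <- bp %in% b1 | bp %in% b2
  if (length(bp) == 0L || !any(bp %in% b1) || !any(bp %in% b2) ||
      !all(in_band))
    stop("infeasible bands: branch points at y = ",
         paste(sort(bp), collapse = ", "), " do not match the bands")
  attr(prof, "branch_levels") <- sort(bp)
  prof
}

#' Generate a cohort of entropy curves with planted branch-level bands
#'
#' Builds `n_proteins` synthetic entropy-derivative curves over the levels
#' `1..n_levels` in which branch activity concentrates inside prescribed
#' disjoint level bands.  Each protein is assigned to one band (cyclically)
#' and receives a common positive amplitude across all levels of its band,
#' plus i.i.d. Gaussian noise everywhere.  Because proteins of different
#' bands have disjoint signal supports, the noise-free correlation matrix
#' is exactly block-structured: 1 within a band, 0 between bands and off
#' the bands.
#'
#' @param seed Integer seed.
#' @param n_proteins Cohort size.
#' @param level_bands List of disjoint increasing integer level ranges
#'   within `1..n_levels`.
#' @param n_levels Number of derivative levels per curve (default 25).
#' @param noise_sd Standard deviation of the additive noise (default 0.1).
#' @param amplitude_mean,amplitude_sd Per-protein band amplitude is
#'   `abs(rnorm(1, amplitude_mean, amplitude_sd))` (defaults 1 and 0.25).
#' @return List of `entropy_curves` with attributes `bands` (the ground
#'   truth) and `band_of` (band index per protein).
#' @export
planted_cohort <- function(seed, n_proteins, level_bands, n_levels = 25L,
                           noise_sd = 0.1, amplitude_mean = 1,
                           amplitude_sd = 0.25) {
  if (!is.list(level_bands) || length(level_bands) == 0L)
    stop("'level_bands' must be a non-empty list of level ranges")
  bands <- lapply(level_bands, as.integer)
  flat <- unlist(bands)
  if (anyDuplicated(flat)) stop("level bands must be disjoint")
  if (any(flat < 1L) || any(flat > n_levels))
    stop("bands must lie within 1..", n_levels)
  with_pinned_seed(seed, {
    band_of <- rep_len(seq_along(bands), n_proteins)
    curves <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      amp <- abs(stats::rnorm(1, amplitude_mean, amplitude_sd))
      sp <- if (noise_sd > 0) stats::rnorm(n_levels, 0, noise_sd)
            else numeric(n_levels)
      sp[bands[[band_of[i]]]] <- sp[bands[[band_of[i]]]] + amp
      curves[[i]] <- new_entropy_curves(sp, id = sprintf("cur%04d", i))
    }
    attr(curves, "bands") <- bands
    attr(curves, "band_of") <- band_of
    curves
  })
}
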