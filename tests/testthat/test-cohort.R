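make_curves <- function(mat) {
  # rows = proteins, columns = derivative levels
  lapply(seq_len(nrow(mat)), function(i)
    anis:::new_entropy_curves(mat[i, ], id = paste0("p", i)))
}

test_that("level vectors collect per-protein derivatives with membership", {
  co <- make_curves(matrix(seq_len(27), nrow = 3, byrow = TRUE))
  lv <- build_level_vectors(co, min_proteins = 3)
  expect_equal(lv$levels, 1:9)
  expect_true(all(vapply(lv$values, length, 1L) == 3L))
  # entries equal the per-protein curves elementwise
  for (y in lv$levels)
    expect_equal(lv$values[[match(y, lv$levels)]],
                 vapply(co, function(cu) cu$S_prime[y], 1))

  # a protein lacking a level is absent from that level's membership
  co2 <- c(co, make_curves(matrix(1:3, nrow = 1)))
  lv2 <- build_level_vectors(co2, min_proteins = 3)
  expect_equal(lv2$members[[1]], 1:4)
  expect_equal(lv2$members[[9]], 1:3)

  expect_error(build_level_vectors(co, min_proteins = 10),
               "at least 10")
})

test_that("correlation matrix is the normalized inner product", {
  co <- make_curves(rbind(c(1, 1, 0), c(2, 2, 0), c(3, 3, 0),
                          c(1, 1, 0), c(2, 2, 1)))
  lv <- build_level_vectors(co, min_proteins = 2)
  m <- correlation_matrix(lv, min_pair = 2)
  # identical vectors correlate at exactly 1
  expect_identical(m$r[1, 2], 1)
  expect_identical(unname(diag(m$r)), rep(1, 3))
  expect_identical(m$r, t(m$r))

  # orthogonal vectors give 0
  co2 <- make_curves(rbind(c(1, 0), c(0, 1)))
  lv2 <- build_level_vectors(co2, min_proteins = 2)
  m2 <- correlation_matrix(lv2, min_pair = 2)
  expect_equal(m2$r[1, 2], 0)

  # random vectors against the textbook cosine
  set.seed(61)
  mat <- matrix(rnorm(5 * 4), nrow = 5)
  lv3 <- build_level_vectors(make_curves(mat), min_proteins = 2)
  m3 <- correlation_matrix(lv3, min_pair = 2)
  for (a in 1:3) for (b in (a + 1):4)
    expect_equal(m3$r[a, b], oracle_cosine(mat[, a], mat[, b]),
                 tolerance = 1e-12)
  expect_true(max(abs(m3$r)) <= 1 + 1e-12)

  # zero-norm vectors are masked with a message
  mat0 <- cbind(rnorm(5), 0, rnorm(5))
  expect_message(
    m4 <- correlation_matrix(build_level_vectors(make_curves(mat0),
                                                 min_proteins = 2),
                             min_pair = 2),
    "zero-norm")
  expect_true(all(is.na(m4$r[2, ])))
})

test_that("Cauchy-Schwarz bound holds on random cohorts", {
  set.seed(62)
  for (rep in 1:10) {
    mat <- matrix(rnorm(30 * 8, sd = runif(1, 0.1, 5)), nrow = 30)
    lv <- build_level_vectors(make_curves(mat), min_proteins = 5)
    m <- correlation_matrix(lv, min_pair = 5)
    expect_true(max(abs(m$r), na.rm = TRUE) <= 1 + 1e-12)
    expect_identical(unname(diag(m$r)), rep(1, ncol(mat)))
  }
})

test_that("threshold masks are strict, monotone and unit-diagonal", {
  set.seed(63)
  mat <- matrix(rnorm(40 * 6), nrow = 40)
  m <- correlation_matrix(build_level_vectors(make_curves(mat),
                                              min_proteins = 5),
                          min_pair = 5)
  off <- m$r; diag(off) <- NA
  tmax <- max(off, na.rm = TRUE)
  # t just below the largest off-diagonal isolates the argmax pair
  mk <- threshold_mask(m, tmax - 1e-9)
  expect_equal(sum(mk) - nrow(mk), 2L)
  # exceeding is strict: at t == tmax the pair is excluded
  if (tmax > 0 && tmax < 1)
    expect_equal(sum(threshold_mask(m, tmax)) - nrow(mk), 0L)
  # monotonicity of masks in t
  m1 <- threshold_mask(m, 0.2); m2 <- threshold_mask(m, 0.6)
  expect_true(all(m2 <= m1))
  # nothing exceeds 0.999 here
  expect_equal(threshold_mask(m, 0.999), diag(nrow(mk)),
               ignore_attr = TRUE)
  expect_error(threshold_mask(m, 0), "between 0 and 1")
  expect_error(threshold_mask(m, 1), "between 0 and 1")
})

test_that("CSA detection partitions the diagonal into maximal squares", {
  expect_equal(detect_csa(diag(6L)),
               data.frame(y_start = 1:6, y_end = 1:6))
  expect_equal(detect_csa(matrix(1L, 5, 5)),
               data.frame(y_start = 1, y_end = 5))
  expect_error(detect_csa(matrix(c(1L, 1L, 0L, 1L), 2)), "symmetric")

  set.seed(64)
  for (rep in 1:50) {
    mask <- random_mask(sample(5:15, 1))
    expect_equal(detect_csa(mask), oracle_csa(mask))
  }
})

test_that("stability scan finds the first repeated block structure", {
  co <- planted_cohort(seed = 3, n_proteins = 120,
                       level_bands = list(3:7, 14:18), n_levels = 22,
                       noise_sd = 0.1)
  m <- correlation_matrix(build_level_vectors(co))
  res <- stability_scan(m)
  expect_true(res$stable)
  blocks <- res$blocks
  expect_true(any(blocks$y_start <= 3 & blocks$y_end >= 7))
  expect_true(any(blocks$y_start <= 14 & blocks$y_end >= 18))
  # blocks are disjoint and ordered
  expect_true(all(blocks$y_start[-1] > blocks$y_end[-nrow(blocks)]))

  # a matrix whose mask never changes stabilizes at the second threshold
  co0 <- planted_cohort(seed = 4, n_proteins = 50,
                        level_bands = list(2:4), n_levels = 8,
                        noise_sd = 0)
  m0 <- suppressMessages(
    correlation_matrix(build_level_vectors(co0), min_pair = 10))
  res0 <- stability_scan(m0, thresholds = c(0.9, 0.5, 0.1))
  expect_true(res0$stable)
  expect_equal(res0$threshold, 0.9)

  expect_error(stability_scan(m, thresholds = 0.5), "length")
  expect_error(stability_scan(m, thresholds = c(0.1, 0.5)), "decreasing")
  expect_error(stability_scan(m, thresholds = c(0.9, 0.5, 0.5)),
               "decreasing")
})

test_that("matrix, mask and CSA exports are readable TSV", {
  co <- planted_cohort(seed = 5, n_proteins = 40, level_bands = list(2:4),
                       n_levels = 10)
  sc <- csa_scan(co, min_proteins = 10, min_pair = 10)
  pm <- withr::local_tempfile(); pk <- withr::local_tempfile()
  pc <- withr::local_tempfile()
  write_cohort_matrix(sc$matrix, pm)
  write_mask(threshold_mask(sc$matrix, 0.5), pk)
  write_csa(sc$result, pc)
  tm <- read.delim(pm, check.names = FALSE)
  expect_equal(nrow(tm), length(sc$matrix$levels))
  tc <- read.delim(pc)
  expect_true(all(c("y_start", "y_end", "stable_threshold") %in% names(tc)))
})
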