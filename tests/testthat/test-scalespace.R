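test_that("inscribed height solves the analytic cases", {
  # constant F: the minimum is attained at z = x with weight 1
  expect_equal(inscribed_height(rep(7, 40), 10, 3), 7, tolerance = 1e-12)
  # all-zero F
  expect_equal(inscribed_height(rep(0, 40), 10, 3), 0)
  # impulse: F(z) * exp((z - j0)^2 / 2y^2) is constant in z
  prof <- planted_profile("impulse", n = 80, j0 = 40, c = 120)
  for (y in c(1, 5, 13)) {
    sp <- smoothed_profile(prof, y)
    expect_equal(inscribed_height(sp, 40, y) * y * sqrt(2 * pi), 120,
                 tolerance = 1e-9)
  }
  # mismatched scale is refused
  expect_error(inscribed_height(smoothed_profile(prof, 2), 40, 3),
               "scale")
})

test_that("inscribed height equals exhaustive minimization over the grid", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(25:50, 1)
    pr <- random_profile(n)
    fld <- height_field(pr)
    y <- sample(seq_len(n %/% 2), 1)
    for (x in sample.int(n, 6)) {
      expect_equal(fld$H[y, x],
                   oracle_inscribed(pr$values, pr$positions, n, x, y),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("height field is bounded by the smoothed profile and consistent", {
  set.seed(42)
  pr <- random_profile(50)
  fld <- height_field(pr)
  expect_true(all(fld$H >= 0))
  expect_true(all(fld$H <= fld$F * (1 + 1e-12)))
  # every entry equals the single-point operation
  y <- 7
  sp <- smoothed_profile(pr, y)
  hx <- vapply(1:50, function(x) inscribed_height(sp, x, y), 1)
  expect_identical(unname(fld$H[y, ]), hx)
  # impulse rows decrease in y
  imp <- height_field(planted_profile("impulse", n = 60, j0 = 30, c = 90))
  expect_true(all(diff(imp$H[, 30]) < 0))
  # constant-profile rows are flat in the interior
  flat <- height_field(anis:::new_freq_profile(rep(10, 56), n = 60))
  mid <- flat$H[3, 25:35]
  expect_lt(max(mid) - min(mid), 1e-6 * max(mid))
})

test_that("level maxima obey the plateau and endpoint rules", {
  fake <- structure(list(id = "t", n = 10, delta = 1L, y_levels = 1L,
                         H = matrix(c(1, 2, 2, 2, 1, 0, 0, 1, 0, 0), 1),
                         F = NULL), class = "height_field")
  expect_equal(level_maxima(fake, 1), c(3L, 8L))
  # endpoint strictly above its single neighbour is a maximum
  fake$H <- matrix(c(5, 4, 3, 2, 1, 1, 1, 1, 1, 2), 1)
  expect_equal(level_maxima(fake, 1), c(1L, 10L))
  # all-zero rows yield no maxima
  fake$H <- matrix(0, 1, 10)
  expect_equal(level_maxima(fake, 1), integer(0))

  imp <- height_field(planted_profile("impulse", n = 60, j0 = 30, c = 90))
  for (y in c(1, 10, 25)) expect_equal(level_maxima(imp, y), 30L)

  two <- height_field(planted_profile("two_impulse", n = 100,
                                      j1 = 30, j2 = 70, c = 90))
  expect_equal(level_maxima(two, 2), c(30L, 70L))
})

test_that("trees track maxima across levels and agree with the tracker", {
  imp <- build_elis_tree(height_field(
    planted_profile("impulse", n = 60, j0 = 30, c = 90)))
  expect_length(imp$roots, 1L)
  expect_length(tree_nodes(imp), 1L)
  expect_null(imp$roots[[1]]$branch_point)

  merge_levels <- vapply(c(14, 28, 48), function(sep) {
    fld <- height_field(planted_profile("two_impulse", n = 110,
                                        j1 = 55 - sep / 2,
                                        j2 = 55 + sep / 2, c = 90))
    tr <- build_elis_tree(fld)
    expect_length(tree_nodes(tr), 3L)
    bp <- tr$roots[[1]]$branch_point
    # the tracker: highest level with two strict maxima, merged above
    per <- oracle_maxima_per_level(fld)
    expect_lte(abs(unname(bp["y0"]) - (max(which(per == 2)) + 1L)), 1L)
    unname(bp["y0"])
  }, 1)
  expect_true(all(diff(merge_levels) > 0))
})

test_that("tree nesting and disjointness hold on random profiles", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(40:90, 1)
    tr <- build_elis_tree(height_field(random_profile(n, spikes = 4)))
    check <- function(nd) {
      expect_true(nd$interval[1] <= nd$interval[2])
      if (length(nd$children)) {
        ivs <- t(vapply(nd$children, function(ch) ch$interval, c(1, 1)))
        expect_true(all(ivs[, 1] >= nd$interval[1]))
        expect_true(all(ivs[, 2] <= nd$interval[2]))
        if (nrow(ivs) > 1)
          expect_true(all(ivs[-1, 1] > ivs[-nrow(ivs), 2]))
        for (ch in nd$children) {
          expect_lt(ch$y_birth, nd$y_death)
          if (!is.null(ch$branch_point))
            expect_lt(ch$branch_point["y0"], nd$branch_point["y0"])
          check(ch)
        }
      }
    }
    for (r in tr$roots) check(r)
    # intervals at any level are disjoint and ordered
    for (y in c(1, n %/% 4, n %/% 2)) {
      iv <- elis_at_level(tr, max(1, y))
      if (nrow(iv) > 1)
        expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
    }
  }
})

test_that("level sections refine upward and rerun serialization is identical", {
  set.seed(45)
  pr <- random_profile(70, spikes = 4)
  tr <- build_elis_tree(height_field(pr))
  top <- elis_at_level(tr, tr$y_max)
  bot <- elis_at_level(tr, 1)
  for (i in seq_len(nrow(bot))) {
    inside <- top$start <= bot$start[i] & bot$end[i] <= top$end
    expect_true(any(inside))
  }
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_elis_tree(tr, p1)
  write_elis_tree(build_elis_tree(height_field(pr)), p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(elis_at_level(tr, 0), "1..")
  expect_error(elis_at_level(tr, tr$y_max + 1), "1..")
})

test_that("an all-zero field yields an empty forest with a warning", {
  zero <- anis:::new_freq_profile(rep(0, 26), n = 30)
  fld <- height_field(zero)
  expect_warning(tr <- build_elis_tree(fld), "no local maxima")
  expect_length(tr$roots, 0L)
})

test_that("newick rendering reflects the hierarchy", {
  two <- build_elis_tree(height_field(
    planted_profile("two_impulse", n = 100, j1 = 30, j2 = 70, c = 90)))
  nk <- as_newick(two)
  expect_match(nk, "^\\(.*,.*\\)1-100:")
  expect_match(nk, ";$")
})
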