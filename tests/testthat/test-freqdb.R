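test_that("length filtering is inclusive and preserves input order", {
  fa <- write_tmp_fasta(c(
    ">short", paste(rep("A", 40), collapse = ""),
    ">mid", paste(rep("C", 100), collapse = ""),
    ">long", paste(rep("D", 500), collapse = "")))
  recs <- scan_database(fa, 50, 400)
  expect_equal(recs$id, "mid")
  expect_equal(recs$length, 100L)

  fa2 <- write_tmp_fasta(c(">edge", paste(rep("G", 50), collapse = "")))
  expect_equal(nrow(scan_database(fa2, 50, 400)), 1L)

  fa3 <- write_tmp_fasta(character(0))
  expect_warning(empty <- scan_database(fa3, 50, 400), "no records")
  expect_equal(nrow(empty), 0L)

  expect_error(scan_database(fa, 100, 50), "min_len")
  expect_error(scan_database("/nonexistent/x.fasta", 50, 400), "not found")
})

test_that("duplicate ids are rejected and residues are upper-cased", {
  fa <- write_tmp_fasta(c(">a", "ACDEF", ">a", "GHIKL"))
  expect_error(scan_database(fa, 5, 10), "duplicate")
  fa2 <- write_tmp_fasta(c(">a desc", "acdefg"))
  recs <- scan_database(fa2, 5, 10)
  expect_equal(recs$residues, "ACDEFG")
  expect_equal(recs$id, "a")
})

test_that("pentapeptide counting slides by one and matches a naive re-scan", {
  tab <- count_pentapeptides(c(p = "AAAAAA"))
  expect_equal(tab$counts, c(AAAAA = 2L))
  expect_equal(tab$n_fragments_total, 2L)

  tab2 <- count_pentapeptides(c(p = "ACDEF"))
  expect_equal(tab2$counts, c(ACDEF = 1L))

  # records below window size contribute nothing
  tab3 <- count_pentapeptides(c(a = "ACD", b = "ACDEF"))
  expect_equal(tab3$n_fragments_total, 1L)

  set.seed(11)
  seqs <- vapply(sample(10:60, 50, replace = TRUE), function(n)
    paste(sample(AA20, n, replace = TRUE), collapse = ""), "")
  tab4 <- count_pentapeptides(seqs)
  expect_identical(tab4$counts, oracle_count(seqs))
  expect_equal(sum(tab4$counts), tab4$n_fragments_total)
})

test_that("non-canonical residues skip the containing windows", {
  expect_message(tab <- count_pentapeptides(c(p = "ACDEFXACDEF")),
                 "skipped")
  # windows touching the X (positions 2..6) are dropped
  expect_equal(tab$n_fragments_total, 2L)
  expect_equal(tab$n_windows_skipped, 5L)
  expect_equal(unname(tab$counts["ACDEF"]), 2L)
})

test_that("homopolymer database conserves window counts", {
  lens <- c(10L, 25L, 7L)
  tab <- count_pentapeptides(vapply(lens, function(n)
    paste(rep("L", n), collapse = ""), ""))
  expect_equal(unname(tab$counts["LLLLL"]), sum(lens - 4L))
  expect_equal(total_frequency(tab, "LLLLL", 0), sum(lens - 4L))
})

test_that("Hamming balls have closed-form sizes and correct membership", {
  expect_equal(hamming_neighbors("ACDEF", 0), "ACDEF")
  b1 <- hamming_neighbors("ACDEF", 1)
  expect_length(b1, 1 + 5 * 19)
  expect_false(anyDuplicated(b1) > 0)
  expect_true(all(vapply(b1, hamming_dist, 1, b = "ACDEF") <= 1))

  b2 <- hamming_neighbors("WWWWW", 2)
  expect_length(b2, 1 + 5 * 19 + choose(5, 2) * 19^2)
  expect_true(all(vapply(b2, hamming_dist, 1, b = "WWWWW") <= 2))

  expect_error(hamming_neighbors("ACDEF", 4), "0..3")
  expect_error(hamming_neighbors("ACDE", 1), "5-letter")
})

test_that("total frequency sums the Hamming ball and is monotone in delta", {
  tab <- count_pentapeptides(c(p = "AAAAAA"))
  expect_equal(total_frequency(tab, "AAAAA", 0), 2)
  expect_equal(total_frequency(tab, "CAAAA", 1), 2)

  set.seed(21)
  seqs <- vapply(rep(30, 20), function(n)
    paste(sample(AA20, n, replace = TRUE), collapse = ""), "")
  tab2 <- count_pentapeptides(seqs)
  frags <- c(names(tab2$counts)[1:5], "AAAAA", "WYWYW")
  for (fr in frags) {
    expect_equal(total_frequency(tab2, fr, 0),
                 oracle_phi(tab2, fr, 0))
    expect_equal(total_frequency(tab2, fr, 1),
                 oracle_phi(tab2, fr, 1))
    expect_equal(total_frequency(tab2, fr, 2),
                 oracle_phi(tab2, fr, 2))
    phis <- vapply(0:3, function(d) total_frequency(tab2, fr, d), 1)
    expect_true(all(diff(phis) >= 0))
  }
  expect_warning(z <- total_frequency(tab2, "AXAAA", 1), "non-alphabet")
  expect_equal(z, 0L)
})

test_that("frequency table TSV round-trips bitwise", {
  tab <- count_pentapeptides(c(a = "ACDEFG", b = "ACDEF"))
  p1 <- withr::local_tempfile()
  write_freq_table(tab, p1)
  back <- read_freq_table(p1)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$n_sequences, tab$n_sequences)
  expect_identical(back$n_fragments_total, tab$n_fragments_total)
  expect_identical(back$length_bounds, tab$length_bounds)

  # idempotent re-serialization of a larger random table
  db <- random_database(40, c(30, 80), seed = 5)
  pa <- withr::local_tempfile(); pb <- withr::local_tempfile()
  write_freq_table(db$table, pa)
  write_freq_table(read_freq_table(pa), pb)
  expect_identical(readLines(pa), readLines(pb))
})

test_that("corrupt table files fail with the offending line", {
  p <- withr::local_tempfile()
  writeLines(c("# n_sequences: 1", "# n_fragments_total: 1",
               "# n_windows_skipped: 0", "# length_bounds: 5 5",
               "ACDE\t1"), p)
  expect_error(read_freq_table(p), "line 5")
  writeLines(c("# n_sequences: 1", "# n_fragments_total: 2",
               "# n_windows_skipped: 0", "# length_bounds: 5 5",
               "ACDEF\t1"), p)
  expect_error(read_freq_table(p), "corrupt")
})
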