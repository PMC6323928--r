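test_that("planted terminal repeats are detected with the right mechanism", {
  # 12 bp direct terminal duplication on a 5 kb backbone
  dtr <- make_circular_genome(42, 5000, 12, "direct_terminal")
  call <- detect_circularity(dtr)
  expect_true(call$is_circular)
  expect_equal(call$mechanism, "DTR")
  expect_equal(call$repeat_length, 12L)
  expect_equal(call$five_prime_pos, 0L)
  expect_equal(call$three_prime_pos, 5000L - 12L)
  expect_equal(oracle_dtr_len(dtr$sequence), 12L)

  # same backbone family, no planted repeat
  none <- make_circular_genome(42, 5000, 0)
  expect_false(detect_circularity(none)$is_circular)
  expect_lt(oracle_dtr_len(none$sequence), 10L)

  # 9 bp terminal duplication is below the 10 bp floor
  short <- make_circular_genome(42, 5000, 9, "direct_terminal")
  expect_false(detect_circularity(short)$is_circular)

  # 21 bp inverted repeat within the terminal windows
  itr <- make_circular_genome(2, 5000, 21, "inverted")
  call <- detect_circularity(itr)
  expect_true(call$is_circular)
  expect_equal(call$mechanism, "inverted")
  expect_equal(call$repeat_length, 21L)
  expect_equal(oracle_windowed_repeat_len(itr$sequence, 50, 20,
                                          inverted = TRUE), 21L)

  # 25 bp direct repeat, copies inside the windows but not terminal
  win <- make_circular_genome(3, 5000, 25, "direct_windowed")
  call <- detect_circularity(win)
  expect_true(call$is_circular)
  expect_equal(call$mechanism, "direct_internal")
  expect_equal(call$repeat_length, 25L)
})

test_that("a DTR takes precedence over a windowed repeat", {
  base <- make_circular_genome(11, 4000, 15, "direct_terminal")
  s <- base$sequence
  # add a 30 bp direct repeat inside the windows on top of the 15 bp DTR,
  # clear of the terminal 15 bases so the DTR itself stays intact
  motif <- substr(make_circular_genome(12, 4000, 0)$sequence, 101, 130)
  substr(s, 21, 50) <- motif
  substr(s, 3931, 3960) <- motif
  call <- detect_circularity(viral_contig("both", s))
  expect_true(call$is_circular)
  expect_equal(call$mechanism, "DTR")
})

test_that("N never matches, even against another N", {
  x <- make_circular_genome(5, 3000, 14, "direct_terminal")
  s <- x$sequence
  # corrupt both copies of the DTR with N at the same offset
  substr(s, 7, 7) <- "N"
  substr(s, 3000 - 14 + 7, 3000 - 14 + 7) <- "N"
  call <- detect_circularity(viral_contig("n_case", s))
  # the 14 bp repeat is broken into halves of < 10 bp; no DTR call
  expect_false(call$mechanism == "DTR" && call$repeat_length >= 14L)
  expect_false(call$is_circular)
})

test_that("lengthening a planted terminal repeat never loses the call", {
  prev <- 0L
  for (k in c(10L, 12L, 16L, 24L, 40L)) {
    ct <- make_circular_genome(77, 3000, k, "direct_terminal")
    call <- detect_circularity(ct)
    expect_true(call$is_circular)
    expect_equal(call$repeat_length, k)
    expect_gt(call$repeat_length, prev)
    prev <- call$repeat_length
  }
})

test_that("sequences shorter than twice the window warn and return no call", {
  expect_warning(call <- detect_circularity(strrep("ACGT", 20)), "terminal_window")
  expect_false(call$is_circular)
})

test_that("identical input and parameters give identical calls", {
  ct <- make_circular_genome(9, 2500, 11, "direct_terminal")
  expect_identical(detect_circularity(ct), detect_circularity(ct))
})

test_that("detect_circularity_all annotates contigs and reports 1-based positions", {
  contigs <- list(make_circular_genome(1, 2000, 12, "direct_terminal", id = "c1"),
                  make_circular_genome(1, 2000, 0, id = "c2"))
  names(contigs) <- c("c1", "c2")
  res <- detect_circularity_all(contigs)
  expect_true(res$contigs[["c1"]]$circularity$is_circular)
  expect_false(res$contigs[["c2"]]$circularity$is_circular)
  expect_equal(res$table$five_prime_pos[1], 1L)
  expect_equal(res$table$three_prime_pos[1], 2000L - 12L + 1L)
  expect_true(is.na(res$table$five_prime_pos[2]))
})
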