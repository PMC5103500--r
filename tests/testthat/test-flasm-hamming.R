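test_that("the worked example yields the exact and one-mismatch factor sets", {
  # factors of length 3 of AAGATG: AAG, AGA, GAT, ATG; first and last occur
  # exactly in the text
  r0 <- flasm("ATGGCAAGT", "AAGATG", 3, 0)
  expect_identical(r0$text_end, c(2L, 7L))
  expect_identical(r0$pattern_end, c(5L, 2L))
  expect_identical(r0$distance, c(0L, 0L))
  # with one mismatch allowed, AGA also pairs with AGT
  r1 <- flasm("ATGGCAAGT", "AAGATG", 3, 1)
  expect_true(any(r1$text_end == 8L & r1$pattern_end == 3L & r1$distance == 1L))
  expect_same_tuples(r1, oracle_flasm("ATGGCAAGT", "AAGATG", 3, 1, "hamming"))
})

test_that("identity windows match at distance zero", {
  r <- flasm("ACGT", "ACGT", 4, 1)
  expect_true(any(r$text_end == 3L & r$pattern_end == 3L & r$distance == 0L))
})

test_that("output equals brute-force window enumeration on random instances", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(10:50, 1); m <- sample(5:min(n, 50), 1)
    ell <- sample(2:min(12, m), 1)
    t <- rand_string(n); x <- rand_string(m)
    k <- sample(0:(ell - 1L), 1)
    expect_same_tuples(flasm(t, x, ell, k), oracle_flasm(t, x, ell, k, "hamming"))
  }
  # factor lengths crossing the 64-bit word boundary
  for (rep in 1:8) {
    n <- sample(72:84, 1); m <- sample(70:n, 1)
    ell <- sample(65:70, 1)
    t <- rand_string(n); x <- rand_string(m)
    k <- sample(c(3L, ell %/% 2L, ell - 1L), 1)
    expect_same_tuples(flasm(t, x, ell, k), oracle_flasm(t, x, ell, k, "hamming"))
  }
})

test_that("tuple sets are monotone in the distance threshold", {
  set.seed(5)
  t <- rand_string(40); x <- rand_string(20)
  prev <- NULL
  for (k in c(0L, 2L, 4L, 7L)) {
    cur <- flasm(t, x, 8, k)
    if (!is.null(prev)) {
      key_prev <- paste(prev$text_end, prev$pattern_end, prev$distance)
      key_cur <- paste(cur$text_end, cur$pattern_end, cur$distance)
      expect_true(all(key_prev %in% key_cur))
    }
    prev <- cur
  }
})

test_that("text and pattern roles are symmetric under Hamming", {
  set.seed(9)
  for (rep in 1:10) {
    a <- rand_string(30); b <- rand_string(25)
    ra <- flasm(a, b, 6, 2)
    rb <- flasm(b, a, 6, 2)
    key_ab <- paste(ra$text_end, ra$pattern_end, ra$distance)
    key_ba <- paste(rb$pattern_end, rb$text_end, rb$distance)
    expect_setequal(key_ab, key_ba)
  }
})

test_that("best mode returns the (e, j, i)-minimal element of the full set", {
  set.seed(13)
  for (rep in 1:15) {
    t <- rand_string(35); x <- rand_string(15)
    k <- sample(0:4, 1)
    all_r <- flasm(t, x, 5, k)
    best <- flasm(t, x, 5, k, mode = "best")
    if (nrow(all_r) == 0L) {
      expect_identical(nrow(best), 0L)
    } else {
      expect_identical(nrow(best), 1L)
      ord <- all_r[order(all_r$distance, all_r$text_end, all_r$pattern_end), ]
      expect_identical(best$text_end, ord$text_end[1])
      expect_identical(best$pattern_end, ord$pattern_end[1])
      expect_identical(best$distance, ord$distance[1])
    }
  }
})

test_that("parameter violations are rejected and case is folded", {
  expect_error(flasm("ACGT", "ACG", 4, 0), "factor_length")
  expect_error(flasm("AC", "ACGT", 3, 0), "factor_length")
  expect_error(flasm("ACGT", "ACGT", 4, 4), "max_distance")
  expect_error(flasm("ACGT", "ACGT", 4, -1), "max_distance")
  expect_error(flasm("", "ACGT", 2, 0), "non-empty")
  expect_error(flasm("ACGT", "", 2, 0), "non-empty")
  expect_identical(flasm("acgt", "ACGT", 4, 0)$distance, 0L)
  # the pattern may exceed the text (circular applications depend on it)
  r <- flasm("GATGAA", "AAGATGAAGAT", 6, 0)
  expect_true(any(r$text_end == 5L & r$pattern_end == 7L))
})
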