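test_that("de Bruijn sequences contain every circular q-gram exactly once", {
  for (case_ in list(list(q = 2, ab = c("a", "b")),
                     list(q = 3, ab = c("a", "b")),
                     list(q = 2, ab = c("A", "C", "G", "T")),
                     list(q = 3, ab = c("0", "1")))) {
    q <- case_$q; ab <- case_$ab
    s <- debruijn_sequence(q, ab)
    sigma <- length(ab)
    expect_identical(nchar(s), as.integer(sigma^q))
    circ <- paste0(s, substr(s, 1, q - 1))
    grams <- substring(circ, 1:nchar(s), q:nchar(circ))
    expect_identical(sort(grams), sort(unique(grams)))
    expect_identical(length(unique(grams)), as.integer(sigma^q))
  }
  expect_identical(debruijn_sequence(2, c("a", "b")), "aabb")
  expect_setequal(chars(debruijn_sequence(1, c("G", "A", "T"))), c("G", "A", "T"))
  expect_identical(debruijn_sequence(3, "A"), "AAA")  # degenerate alphabet
})

test_that("q-gram ranking is the bijective base-sigma value", {
  dna <- c("A", "C", "G", "T")
  expect_identical(qgram_rank("AA", dna), 0L)
  expect_identical(qgram_rank("AC", dna), 1L)
  expect_identical(qgram_rank("CA", dna), 4L)
  for (r in 0:63) {
    g <- qgram_unrank(r, 3, dna)
    expect_identical(qgram_rank(g, dna), r)
  }
  expect_error(qgram_rank("AX", dna), "outside the alphabet")
})

test_that("the FLASM-built index matches direct minimisation", {
  expect_identical(build_cm_index("AAC", 2, alphabet = c("A", "C"))$D,
                   c(0L, 0L, 1L, 1L))
  set.seed(404)
  x <- rand_string(32)
  for (model in c("hamming", "edit")) {
    for (q in 2:4) {
      fast <- build_cm_index(x, q, model = model)
      naive <- build_cm_index_naive(x, q, model = model)
      expect_identical(fast$D, naive$D)
    }
  }
})

test_that("exact factors index at zero and extension never raises entries", {
  set.seed(19)
  x <- rand_string(40)
  for (model in c("hamming", "edit")) {
    idx <- build_cm_index(x, 3, model = model)
    st <- seq_len(nchar(x) - 2L)
    facs <- unique(substring(x, st, st + 2L))
    for (f in facs)
      expect_identical(idx$D[qgram_rank(f, idx$alphabet) + 1L], 0L)
    longer <- build_cm_index(paste0(x, rand_string(10)), 3, model = model)
    expect_true(all(longer$D <= idx$D))
  }
})

test_that("index serialisation writes a header plus one row per q-gram", {
  idx <- build_cm_index("ACGTACGT", 2)
  path <- tempfile(fileext = ".tsv")
  write_cm_index(idx, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "# {"))
  expect_identical(length(lines), 2L + 16L)
  tab <- read.delim(path, comment.char = "#")
  expect_identical(tab$distance, idx$D)
  expect_identical(tab$qgram[1], "AA")
})

test_that("index parameters are validated", {
  expect_error(build_cm_index("AC", 3), "exceeds")
  expect_error(build_cm_index("ACGTN", 2), "outside the alphabet")
  expect_error(debruijn_sequence(2, character(0)), "non-empty")
  expect_error(debruijn_sequence(2, c("a", "a")), "distinct")
})
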