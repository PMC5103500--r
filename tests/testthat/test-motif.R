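test_that("a shared core motif is extracted at full quorum", {
  res <- single_motif_extract(c("AACGTT", "CACGTG", "TACGTA"), 4, 0, quorum = 3)
  expect_identical(nrow(res), 1L)
  expect_identical(res$motif, "ACGT")
  expect_identical(res$quorum_count, 3L)
  expect_identical(res$source_seq, 1L)   # lexicographically least source
  expect_identical(res$source_end, 4L)
  expect_identical(res$seq_hits[[1]], c(1L, 1L, 1L))
})

test_that("quorum one returns every distinct factor (self-occurrence counts)", {
  seqs <- c("ACGTT", "GGCAT")
  res <- single_motif_extract(seqs, 3, 0, quorum = 1)
  want <- unique(unlist(lapply(seqs, function(s)
    substring(s, 1:3, 3:5))))
  expect_setequal(res$motif, want)
})

test_that("single extraction equals brute-force enumeration", {
  set.seed(505)
  for (model in c("hamming", "edit")) {
    for (rep in 1:4) {
      seqs <- vapply(1:4, function(i) rand_string(sample(20:30, 1)), "")
      ell <- sample(4:6, 1); k <- sample(0:2, 1)
      quorum <- sample(2:4, 1)
      got <- single_motif_extract(seqs, ell, k, quorum, model = model)
      want <- oracle_single_motifs(seqs, ell, k, quorum, model)
      expect_identical(got$motif, want$motif)
      expect_identical(got$quorum_count, as.integer(want$quorum_count))
    }
  }
})

test_that("box occurrence intervals match the reference scan", {
  expect_identical(box_occurrences("AAATCCC", "AAA", 0)[[1]]$start, 0L)
  expect_identical(box_occurrences("AAATCCC", "AAA", 0)[[1]]$end, 2L)
  # AGA matches AGT with one mismatch at positions 6..8 of the worked text
  occ <- box_occurrences("ATGGCAAGT", "AGA", 1)[[1]]
  expect_true(any(occ$start == 6L & occ$end == 8L & occ$distance == 1L))
  set.seed(77)
  for (model in c("hamming", "edit")) {
    for (rep in 1:5) {
      s <- rand_string(25); box <- rand_string(4)
      k <- sample(0:2, 1)
      got <- box_occurrences(s, box, k, model = model)[[1]]
      want <- oracle_box_occ(s, box, k, model)
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$end, as.integer(want$end))
      expect_identical(got$distance, as.integer(want$distance))
    }
  }
})

test_that("structured motifs respect spacer intervals and quorum", {
  seqs <- c("AAATCCC", "AAATTCCCG", "AAACCC")
  res <- structured_motif_extract(seqs, "(3,0)[1,2](3,0)", quorum = 2)
  expect_true("AAA[1,2]CCC" %in% res$motif)
  row <- res[res$motif == "AAA[1,2]CCC", ]
  expect_identical(row$quorum_count, 2L)  # spacer lengths 1 and 2; 0 fails
  expect_identical(row$seq_occurs[[1]], c(TRUE, TRUE, FALSE))
})

test_that("structured extraction equals brute-force chain enumeration", {
  set.seed(606)
  for (model in c("hamming", "edit")) {
    for (rep in 1:3) {
      seqs <- vapply(1:4, function(i) rand_string(sample(25:40, 1)), "")
      boxes <- cbind(length = c(3L, 4L), k = c(1L, 1L))
      gaps <- cbind(dmin = 1L, dmax = 4L)
      quorum <- 2L
      got <- structured_motif_extract(seqs, list(boxes = boxes, gaps = gaps),
                                      quorum, model = model)
      got_keys <- sort(paste(got$box1, got$box2, sep = "|"))
      want <- oracle_structured(seqs, boxes, gaps, quorum, model)
      expect_identical(got_keys, want$motif_key)
      if (nrow(got)) {
        ord <- match(want$motif_key, paste(got$box1, got$box2, sep = "|"))
        expect_identical(got$quorum_count[ord], as.integer(want$quorum_count))
      }
    }
  }
})

test_that("a single box degenerates to single motif extraction", {
  seqs <- c("AACGTT", "CACGTG", "TACGTA")
  a <- structured_motif_extract(seqs, "(4,0)", quorum = 3)
  b <- single_motif_extract(seqs, 4, 0, quorum = 3)
  expect_identical(a$motif, b$motif)
  expect_identical(a$quorum_count, b$quorum_count)
})

test_that("raising quorum prunes and raising k never removes motifs", {
  set.seed(808)
  seqs <- vapply(1:4, function(i) rand_string(25), "")
  m2 <- single_motif_extract(seqs, 5, 1, quorum = 2)
  m3 <- single_motif_extract(seqs, 5, 1, quorum = 3)
  expect_true(all(m3$motif %in% m2$motif))
  lo <- single_motif_extract(seqs, 5, 1, quorum = 2)
  hi <- single_motif_extract(seqs, 5, 2, quorum = 2)
  expect_true(all(lo$motif %in% hi$motif))
})

test_that("an implanted long motif is recovered across every sequence", {
  # motif length 120 exceeds the machine word; per-copy corruption stays
  # within the matching threshold
  k <- 8L
  base <- random_seqs(10, 500, seed = 99)
  motif <- random_dna(120, seed = 100)
  imp <- implant_single(base, motif, targets = 1:10, subs_per_copy = k %/% 2L,
                        seed = 101)
  res <- single_motif_extract(imp$seqs, 120, k, quorum = 10)
  expect_true(motif %in% res$motif)
  expect_identical(res$quorum_count[res$motif == motif], 10L)
})

test_that("the parameter notation round-trips through the parser", {
  sp <- parse_motif_spec("<(80,15)[5,15](60,10)[5,20](230,20)>")
  expect_identical(sp$boxes[, "length"], c(80L, 60L, 230L))
  expect_identical(sp$boxes[, "k"], c(15L, 10L, 20L))
  expect_identical(sp$gaps[, "dmin"], c(5L, 5L))
  expect_identical(sp$gaps[, "dmax"], c(15L, 20L))
  expect_error(parse_motif_spec("(3,0)(4,1)"), "interval")
  expect_error(parse_motif_spec("(3,3)[1,2](4,1)"), "k < length")
  expect_error(single_motif_extract(c("ACGT", "ACGT"), 3, 0, quorum = 5),
               "quorum")
})
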