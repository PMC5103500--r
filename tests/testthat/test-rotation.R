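test_that("the best pairwise rotation aligns rotated copies exactly", {
  expect_identical(pair_best_rotation("AAGATG", "GATGAA", 6, 0),
                   list(rotation = 2L, distance = 0L))
  s <- "ACGGTCAA"
  expect_identical(pair_best_rotation(s, s, 8, 0),
                   list(rotation = 0L, distance = 0L))
  set.seed(55)
  s <- rand_string(30)
  for (r in c(0, 3, 11, 29)) {
    pb <- pair_best_rotation(s, rotate_string(s, r), 30, 0)
    expect_identical(pb$rotation %% 30L, as.integer(r))
    expect_identical(pb$distance, 0L)
  }
  expect_null(pair_best_rotation("AAAA", "CCCC", 4, 0))
})

test_that("the rotation matrix covers every ordered pair", {
  set.seed(66)
  s1 <- rand_string(24)
  seqs <- c(a = s1, b = rotate_string(s1, 5), c = rotate_string(s1, 11))
  mat <- build_rotation_matrix(seqs, 24, 0)
  expect_identical(dim(mat$distance), c(3L, 3L))
  expect_true(all(mat$distance[upper.tri(mat$distance)] == 0))
  expect_identical(mat$rotation["a", "b"], 5L)
  expect_identical(mat$rotation["a", "c"], 11L)
  # identical sequences: all-zero rotations and distances
  same <- build_rotation_matrix(rep(s1, 3), 24, 0)
  expect_true(all(same$rotation == 0L))
  expect_true(all(same$distance == 0))
  # full-length comparisons of equal-length sequences see the same circular
  # window pairs in both directions, so the best distance is symmetric
  set.seed(67)
  seqs2 <- c(rand_string(20), rand_string(20))
  m2 <- build_rotation_matrix(seqs2, 20, 19)
  expect_identical(m2$distance[1, 2], m2$distance[2, 1])
})

test_that("refinement restores a common frame for pure rotations", {
  set.seed(77)
  anc <- rand_string(40)
  for (rep in 1:5) {
    rots <- sample(0:39, 5)
    seqs <- vapply(rots, function(r) rotate_string(anc, r), "")
    out <- refine_rotations(seqs, factor_length = 40, max_distance = 0)
    expect_identical(length(unique(out)), 1L)
    expect_identical(unname(out[1]), seqs[1])  # first sequence anchors
  }
})

test_that("outputs are rotations of their inputs (letter content preserved)", {
  set.seed(88)
  seqs <- vapply(1:4, function(i) rand_string(30), "")
  out <- refine_rotations(seqs, factor_length = 12, max_distance = 5)
  rho <- attr(out, "rotations")
  for (i in seq_along(seqs)) {
    expect_identical(unname(out[i]), rotate_string(seqs[i], rho[i]))
    expect_identical(sort(chars(out[i])), sort(chars(seqs[i])))
  }
  # two sequences: the first stays put
  two <- refine_rotations(c("ACGTAC", rotate_string("ACGTAC", 2)),
                          factor_length = 6, max_distance = 0)
  expect_identical(unname(two[1]), "ACGTAC")
  expect_identical(unname(two[2]), "ACGTAC")
})

test_that("unmatched pairs carry the infinity sentinel and still merge", {
  seqs <- c("AAAAAA", "AAATAA", "CCCCCC")
  mat <- build_rotation_matrix(seqs, 6, 1)
  expect_identical(mat$distance[1, 3], Inf)
  out <- refine_rotations(seqs, matrix = mat)
  expect_identical(length(out), 3L)
  expect_identical(sort(chars(out[3])), sort(chars(seqs[3])))
})

test_that("random rotation fixtures are seed-deterministic and invertible", {
  seqs <- random_seqs(6, 25, seed = 12)
  a <- random_rotate(seqs, seed = 34)
  b <- random_rotate(seqs, seed = 34)
  expect_identical(a, b)
  for (i in 1:6) {
    expect_identical(unname(rotate_string(a$seqs[i], (25 - a$rotations[i]) %% 25)),
                     unname(seqs[i]))
  }
})
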