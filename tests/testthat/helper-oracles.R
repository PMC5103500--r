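# Independent reference implementations used as test oracles. Everything
# here is plain R working on character/digit vectors -- deliberately
# separate from the package's bit-parallel code paths.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# ---- bit vectors -------------------------------------------------------
# digit-vector arithmetic, bit 0 first (schoolbook carry propagation)

r_bits_shl <- function(bits) c(0L, bits[-length(bits)])

r_bits_add <- function(a, b) {
  l <- length(a)
  out <- integer(l)
  carry <- 0L
  for (p in seq_len(l)) {
    s <- a[p] + b[p] + carry
    out[p] <- s %% 2L
    carry <- s %/% 2L
  }
  out
}

r_bits_value <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

# ---- window distance tables -------------------------------------------

# Hamming distances of all window pairs: rows = pattern ending positions
# ell..m, cols = text ending positions ell..n (1-based ends)
oracle_hamming_table <- function(t, x, ell) {
  tc <- chars(t); xc <- chars(x)
  m <- length(xc); n <- length(tc)
  mm <- outer(xc, tc, "!=")
  ie <- ell:m; je <- ell:n
  acc <- matrix(0L, length(ie), length(je))
  for (o in 0:(ell - 1L)) acc <- acc + mm[ie - o, je - o, drop = FALSE]
  acc
}

# min over start positions s <= j of editdist(t[s..j], win), for every j;
# row DP with the cummin trick for the horizontal (insertion) dependency
oracle_edit_semiglobal <- function(tc, win) {
  n <- length(tc)
  prev <- rep(0L, n + 1L)
  for (i in seq_along(win)) {
    cost <- as.integer(win[i] != tc)
    V <- pmin(prev[1:n] + cost, prev[2:(n + 1L)] + 1L)
    U <- c(i, V - seq_len(n))
    prev <- cummin(U) + 0:n
  }
  prev[2:(n + 1L)]
}

# rows = pattern factor ending positions ell..m, cols = all text ends 1..n
oracle_edit_table <- function(t, x, ell) {
  tc <- chars(t); xc <- chars(x)
  m <- length(xc)
  do.call(rbind, lapply(ell:m, function(fi)
    oracle_edit_semiglobal(tc, xc[(fi - ell + 1L):fi])))
}

# threshold a distance table into the <j, i, e> tuple set (0-based ends)
oracle_tuples <- function(tbl, ell, k, text_cols_from = ell) {
  hit <- which(tbl <= k, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(text_end = integer(0), pattern_end = integer(0),
                      distance = integer(0)))
  out <- data.frame(text_end = text_cols_from + hit[, 2L] - 2L,
                    pattern_end = ell + hit[, 1L] - 2L,
                    distance = tbl[hit])
  out <- out[order(out$text_end, out$pattern_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_flasm <- function(t, x, ell, k, model) {
  if (model == "hamming")
    oracle_tuples(oracle_hamming_table(t, x, ell), ell, k, text_cols_from = ell)
  else
    oracle_tuples(oracle_edit_table(t, x, ell), ell, k, text_cols_from = 1L)
}

expect_same_tuples <- function(got, want) {
  got <- got[order(got$text_end, got$pattern_end), c("text_end", "pattern_end", "distance")]
  rownames(got) <- NULL
  want <- want[order(want$text_end, want$pattern_end), ]
  rownames(want) <- NULL
  expect_equal(got$text_end, want$text_end)
  expect_equal(got$pattern_end, want$pattern_end)
  expect_equal(got$distance, as.integer(want$distance))
}

# ---- circular matching -------------------------------------------------

# per-rotation matcher: (text_end, rotation, distance) triples with e <= k
oracle_acsm <- function(t, x, k, model) {
  m <- nchar(x)
  tc <- chars(t)
  rows <- lapply(0:(m - 1L), function(r) {
    rot <- flasmr::rotate_string(x, r)
    if (model == "hamming") {
      tbl <- oracle_hamming_table(t, rot, m)   # single row: windows of t
      e <- as.integer(tbl[1L, ])
      j0 <- (m:nchar(t)) - 1L
    } else {
      e <- oracle_edit_semiglobal(tc, chars(rot))
      j0 <- seq_along(tc) - 1L
    }
    sel <- which(e <= k)
    if (!length(sel)) return(NULL)
    data.frame(text_end = j0[sel], rotation = r, distance = e[sel])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(text_end = integer(0), rotation = integer(0),
                      distance = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$text_end, out$rotation), ]
  rownames(out) <- NULL
  out
}

# ---- motif occurrence oracles -----------------------------------------

# minimal distance between `motif` and any factor of `s` under the package's
# occurrence semantics (edit: semi-global minimum over factors)
oracle_min_occurrence <- function(s, motif, model) {
  if (model == "hamming") {
    l <- nchar(motif); n <- nchar(s)
    if (l > n) return(Inf)
    min(oracle_hamming_table(s, motif, l)[1L, ])
  } else {
    min(oracle_edit_semiglobal(chars(s), chars(motif)))
  }
}

# brute-force single motif extraction: distinct factors x sequences
oracle_single_motifs <- function(seqs, ell, k, quorum, model) {
  facs <- unique(unlist(lapply(seqs, function(s) {
    st <- seq_len(nchar(s) - ell + 1L)
    substring(s, st, st + ell - 1L)
  })))
  qc <- vapply(facs, function(f)
    sum(vapply(seqs, function(s)
      oracle_min_occurrence(s, f, model) <= k, logical(1))), integer(1))
  out <- data.frame(motif = facs, quorum_count = qc, stringsAsFactors = FALSE)
  out <- out[out$quorum_count >= quorum, , drop = FALSE]
  out <- out[order(-out$quorum_count, out$motif), ]
  rownames(out) <- NULL
  out
}

# box occurrences under the package's documented semantics: per ending
# position, minimal distance (edit: with the smallest minimising start)
oracle_box_occ <- function(s, box, k, model) {
  n <- nchar(s); l <- nchar(box)
  if (model == "hamming") {
    if (l > n)
      return(data.frame(start = integer(0), end = integer(0), distance = integer(0)))
    e <- as.integer(oracle_hamming_table(s, box, l)[1L, ])
    sel <- which(e <= k)
    out <- data.frame(start = sel - 1L, end = sel + l - 2L, distance = e[sel])
  } else {
    sc <- chars(s); bc <- chars(box)
    res <- lapply(seq_len(n), function(j) {
      cand <- vapply(seq_len(j + 1L) - 1L, function(s0) {  # 0-based starts 0..j
        sub <- if (s0 > j - 1L) character(0) else sc[(s0 + 1L):j]
        drop(utils::adist(paste(sub, collapse = ""), box))
      }, numeric(1))
      e <- min(cand)
      if (e > k) return(NULL)
      data.frame(start = which.min(cand) - 1L, end = j - 1L, distance = as.integer(e))
    })
    res <- res[!vapply(res, is.null, logical(1))]
    out <- if (length(res)) do.call(rbind, res)
           else data.frame(start = integer(0), end = integer(0), distance = integer(0))
  }
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# brute-force structured extraction following the package's occurrence
# semantics; returns data.frame(motif_key, quorum_count)
oracle_structured <- function(seqs, boxes, gaps, quorum, model) {
  beta <- nrow(boxes)
  # candidates: exact chains anywhere in the inputs
  cands <- unique(unlist(lapply(seqs, function(s) {
    enumerate_exact_chains(s, boxes, gaps)
  })))
  if (!length(cands))
    return(data.frame(motif_key = character(0), quorum_count = integer(0)))
  qc <- vapply(cands, function(key) {
    bs <- strsplit(key, "|", fixed = TRUE)[[1]]
    sum(vapply(seqs, function(s) {
      occ <- lapply(seq_len(beta), function(b)
        oracle_box_occ(s, bs[b], boxes[b, "k"], model))
      brute_has_chain(occ, gaps)
    }, logical(1)))
  }, integer(1))
  out <- data.frame(motif_key = cands, quorum_count = qc,
                    stringsAsFactors = FALSE)
  out <- out[out$quorum_count >= quorum, , drop = FALSE]
  out <- out[order(out$motif_key), ]
  rownames(out) <- NULL
  out
}

enumerate_exact_chains <- function(s, boxes, gaps) {
  beta <- nrow(boxes)
  n <- nchar(s)
  grow <- function(b, end0) {
    l <- boxes[b, "length"]
    starts <- if (b == 1L) 0:(n - l)
              else {
                lo <- end0 + gaps[b - 1L, "dmin"] + 1L
                hi <- min(end0 + gaps[b - 1L, "dmax"] + 1L, n - l)
                if (lo > hi) return(character(0))
                lo:hi
              }
    unlist(lapply(starts, function(s0) {
      str <- substr(s, s0 + 1L, s0 + l)
      if (b == beta) return(str)
      tails <- grow(b + 1L, s0 + l - 1L)
      if (!length(tails)) return(character(0))
      paste(str, tails, sep = "|")
    }))
  }
  if (n < boxes[1L, "length"]) return(character(0))
  grow(1L, NA)
}

brute_has_chain <- function(occ_list, gaps) {
  reach <- occ_list[[1L]]$end
  if (!length(reach)) return(FALSE)
  for (b in seq_len(length(occ_list) - 1L)) {
    nxt <- occ_list[[b + 1L]]
    if (!nrow(nxt)) return(FALSE)
    ok <- vapply(seq_len(nrow(nxt)), function(r)
      any(nxt$start[r] - reach - 1L >= gaps[b, "dmin"] &
          nxt$start[r] - reach - 1L <= gaps[b, "dmax"]), logical(1))
    reach <- nxt$end[ok]
    if (!length(reach)) return(FALSE)
  }
  TRUE
}

# ---- misc --------------------------------------------------------------

rand_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
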