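#' Seeded random sequence generators
#'
#' `random_dna()` draws a uniform random sequence over the alphabet;
#' `random_seqs()` draws several. Both are pure functions of their
#' parameters and the seed: the caller's RNG stream is never disturbed, and
#' the same seed always reproduces the same output.
#'
#' @param n sequence length.
#' @param N number of sequences.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param alphabet letters to draw from (default DNA).
#' @return `random_dna()` a string; `random_seqs()` a named character
#'   vector.
#' @examples
#' random_dna(12, seed = 1)
#' @export
random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  stopifnot(n >= 1)
  with_seed(seed, paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

#' @rdname random_dna
#' @export
random_seqs <- function(N, n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  stopifnot(N >= 1)
  with_seed(seed, {
    out <- vapply(seq_len(N), function(i) random_dna(n, alphabet = alphabet),
                  character(1))
    names(out) <- paste0("seq", seq_len(N))
    out
  })
}

#' Corrupt a string with a fixed number of substitutions
#'
#' Replaces `count` distinct positions with different letters, so the
#' result is at Hamming distance exactly `count` from the input.
#'
#' @param x a string.
#' @param count number of substitutions, `0 <= count <= nchar(x)`.
#' @param seed integer seed.
#' @param alphabet replacement letters.
#' @return The corrupted string.
#' @export
substitute_letters <- function(x, count, seed = NULL,
                               alphabet = c("A", "C", "G", "T")) {
  x <- as_seq(x)
  count <- as.integer(count)
  stopifnot(count >= 0L, count <= nchar(x))
  if (count == 0L) return(x)
  with_seed(seed, {
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    pos <- sample.int(length(chars), count)
    for (p in pos) {
      choices <- setdiff(alphabet, chars[p])
      chars[p] <- sample(choices, 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Implant motif instances into background sequences
#'
#' `implant_single()` writes one copy of `motif` into each target sequence
#' at a random position; `implant_structured()` writes one instance of a
#' structured motif (the boxes separated by spacers drawn uniformly from
#' the given intervals, spacer letters left as background). One designated
#' copy is implanted exactly — a strictly valid motif must occur somewhere
#' with zero errors — and every other copy is corrupted with exactly
#' `subs_per_copy` (per box, `subs_per_box`) substitutions, keeping each
#' copy within the intended occurrence threshold of the canonical motif.
#' Ground-truth positions are returned for recovery checks.
#'
#' @param seqs background sequences (e.g. from [random_seqs()]).
#' @param motif canonical single motif string.
#' @param boxes character vector of canonical box strings.
#' @param gaps integer matrix with columns `dmin`, `dmax` (one row per
#'   spacer; `nrow = length(boxes) - 1`).
#' @param targets indices of the sequences to implant into (one instance
#'   each).
#' @param subs_per_copy,subs_per_box substitutions applied to each
#'   non-exact copy (scalar, or per box for `subs_per_box`).
#' @param exact_copy index (into `targets`) of the copy implanted without
#'   corruption; default the first.
#' @param seed integer seed; all placement, spacer and corruption choices
#'   derive from it.
#' @return A list with `seqs` (sequences with implants) and `truth`, a
#'   data.frame of ground-truth placements: target sequence, box starts
#'   (0-based, comma-separated for structured), sampled spacer lengths and
#'   the substitution count applied.
#' @examples
#' base <- random_seqs(4, 60, seed = 1)
#' implant_single(base, "ACGTACGT", targets = 1:3, subs_per_copy = 1,
#'                seed = 2)$truth
#' @export
implant_single <- function(seqs, motif, targets, subs_per_copy = 0L,
                           exact_copy = 1L, seed = NULL) {
  motif <- as_seq(motif, "motif")
  res <- implant_structured(seqs, boxes = motif,
                            gaps = matrix(integer(0), 0, 2,
                                          dimnames = list(NULL, c("dmin", "dmax"))),
                            targets = targets, subs_per_box = subs_per_copy,
                            exact_copy = exact_copy, seed = seed)
  res
}

#' @rdname implant_single
#' @export
implant_structured <- function(seqs, boxes, gaps, targets, subs_per_box = 0L,
                               exact_copy = 1L, seed = NULL) {
  seqs <- as_seqs(seqs)
  boxes <- vapply(boxes, as_seq, character(1), USE.NAMES = FALSE)
  beta <- length(boxes)
  if (is.null(dim(gaps))) gaps <- matrix(as.integer(gaps), ncol = 2)
  if (nrow(gaps) != beta - 1L)
    stop("need one gap interval per adjacent box pair", call. = FALSE)
  targets <- as.integer(targets)
  if (anyDuplicated(targets) || any(targets < 1L | targets > length(seqs)))
    stop("targets must be distinct sequence indices", call. = FALSE)
  subs_per_box <- rep_len(as.integer(subs_per_box), beta)
  if (any(subs_per_box >= nchar(boxes)))
    stop("per-box corruption must be smaller than the box length", call. = FALSE)
  lens <- nchar(boxes)
  with_seed(seed, {
    truth <- vector("list", length(targets))
    for (ti in seq_along(targets)) {
      tgt <- targets[ti]
      s <- seqs[tgt]
      g <- if (beta > 1L)
        vapply(seq_len(beta - 1L), function(b)
          sample(gaps[b, 1]:gaps[b, 2], 1L), integer(1))
      else integer(0)
      total <- sum(lens) + sum(g)
      if (total > nchar(s))
        stop("structured motif instance does not fit in sequence ", tgt,
             call. = FALSE)
      start0 <- sample.int(nchar(s) - total + 1L, 1L) - 1L  # 0-based
      subs <- if (ti == exact_copy) rep(0L, beta) else subs_per_box
      pos <- start0
      starts <- integer(beta)
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      for (b in seq_len(beta)) {
        copy <- substitute_letters(boxes[b], subs[b])
        starts[b] <- pos
        chars[(pos + 1L):(pos + lens[b])] <- strsplit(copy, "", fixed = TRUE)[[1]]
        pos <- pos + lens[b] + if (b < beta) g[b] else 0L
      }
      seqs[tgt] <- paste(chars, collapse = "")
      truth[[ti]] <- data.frame(
        target = tgt,
        box_starts = paste(starts, collapse = ","),
        gaps = paste(g, collapse = ","),
        substitutions = paste(subs, collapse = ","),
        stringsAsFactors = FALSE)
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
}
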