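#' Single motif extraction with quorum
#'
#' Report every length-`factor_length` factor of the input sequences that
#' k-occurs (has a factor within `max_distance` under `model`) in at least
#' `quorum` of the sequences. All reported motifs are strictly valid: each
#' occurs with zero errors at its source position in some input sequence.
#' A factor trivially 0-occurs in its own sequence, so the source sequence
#' always counts towards the quorum. Occurrence counting runs the FLASM
#' core over all ordered sequence pairs, so motif lengths beyond the
#' machine word are fully supported.
#'
#' @param seqs character vector (optionally named) of N >= 2 sequences.
#' @param factor_length motif length \eqn{\ell}, at most the shortest
#'   sequence length.
#' @param max_distance occurrence threshold k, `k < factor_length`.
#' @param quorum minimum number of sequences a motif must k-occur in,
#'   `1 <= quorum <= N`.
#' @param model `"hamming"` or `"edit"`.
#'
#' @return A `data.frame` sorted by decreasing `quorum_count` then motif
#'   string, with one row per distinct motif: `motif`, `source_seq`
#'   (1-based index of the lexicographically least exact source),
#'   `source_end` (0-based ending position there), `quorum_count`, and a
#'   list column `seq_hits` giving, per input sequence, the number of text
#'   ending positions with a k-occurrence.
#'
#' @examples
#' single_motif_extract(c("AACGTT", "CACGTG", "TACGTA"), 4, 0, quorum = 3)
#' @export
single_motif_extract <- function(seqs, factor_length, max_distance, quorum,
                                 model = c("hamming", "edit")) {
  model <- match.arg(model)
  seqs <- as_seqs(seqs)
  N <- length(seqs)
  if (N < 2L) stop("at least two sequences are required", call. = FALSE)
  ell <- as.integer(factor_length)
  k <- as.integer(max_distance)
  quorum <- as.integer(quorum)
  if (quorum < 1L || quorum > N) stop("quorum must be in [1, N]", call. = FALSE)
  if (ell > min(nchar(seqs)))
    stop("factor_length exceeds the shortest sequence", call. = FALSE)
  if (k < 0L || k >= ell) stop("max_distance must satisfy 0 <= k < factor_length", call. = FALSE)

  rows <- vector("list", N)
  for (i in seq_len(N)) {
    m <- nchar(seqs[i])
    ends <- ell:m                        # 1-based ending positions
    occ <- matrix(FALSE, N, length(ends))
    hits <- matrix(0L, N, length(ends))
    for (j in seq_len(N)) {
      pr <- flasm_profile(text = seqs[j], pattern = seqs[i],
                          factor_length = ell, max_distance = k, model = model)
      occ[j, ] <- pr$min_e[ends] <= k
      hits[j, ] <- pr$hits[ends]
    }
    qc <- colSums(occ)
    keep <- which(qc >= quorum)
    if (length(keep) == 0L) next
    motifs <- substring(seqs[i], ends[keep] - ell + 1L, ends[keep])
    rows[[i]] <- data.frame(motif = motifs, source_seq = i,
                            source_end = ends[keep] - 1L,
                            quorum_count = as.integer(qc[keep]),
                            hit_col = I(lapply(keep, function(cix) hits[, cix])),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty_single_motif_df())
  # dedupe by motif string, keeping the lexicographically least source
  out <- out[order(out$motif, out$source_seq, out$source_end), , drop = FALSE]
  out <- out[!duplicated(out$motif), , drop = FALSE]
  out <- out[order(-out$quorum_count, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  names(out)[names(out) == "hit_col"] <- "seq_hits"
  out
}

empty_single_motif_df <- function() {
  data.frame(motif = character(0), source_seq = integer(0),
             source_end = integer(0), quorum_count = integer(0),
             seq_hits = I(list()), stringsAsFactors = FALSE)
}

#' Occurrence intervals of one motif box in each sequence
#'
#' For a fixed box string, list the 0-based inclusive `(start, end)`
#' intervals at which the box k-occurs in each sequence, sorted by start.
#' Under Hamming the start is `end - nchar(box) + 1`; under the edit model
#' the start is the one attaining the minimal distance for that ending
#' position (smallest start on ties). This is the primitive the structured
#' motif chain join is built on.
#'
#' @param seqs character vector of sequences.
#' @param box the box string.
#' @param max_distance occurrence threshold, `< nchar(box)`.
#' @param model `"hamming"` or `"edit"`.
#' @return A list (one entry per sequence) of data.frames with integer
#'   columns `start`, `end`, `distance`.
#' @examples
#' box_occurrences("AAATCCC", "AAA", 0)
#' @export
box_occurrences <- function(seqs, box, max_distance,
                            model = c("hamming", "edit")) {
  model <- match.arg(model)
  box <- as_seq(box, "box")
  k <- as.integer(max_distance)
  if (k < 0L || k >= nchar(box))
    stop("max_distance must satisfy 0 <= k < nchar(box)", call. = FALSE)
  seqs <- as_seqs(seqs)
  lapply(unname(seqs), function(s) {
    if (model == "hamming") cpp_box_occ_hamming(s, box, k)
    else cpp_box_occ_edit(s, box, k)
  })
}

#' Parse structured-motif parameter notation
#'
#' Parses the standard notation
#' `(l1,k1)[dmin1,dmax1](l2,k2)...[dminB-1,dmaxB-1](lB,kB)` into a
#' specification usable by [structured_motif_extract()]: `beta` box
#' `(length, threshold)` pairs separated by `beta - 1` spacer-length
#' intervals.
#'
#' @param spec the parameter string.
#' @return A list with integer matrices `boxes` (columns `length`, `k`) and
#'   `gaps` (columns `dmin`, `dmax`; zero rows when `beta = 1`).
#' @examples
#' parse_motif_spec("(3,0)[1,2](3,0)")
#' @export
parse_motif_spec <- function(spec) {
  s <- gsub("[[:space:]<>]", "", spec)
  box_m <- gregexpr("\\(([0-9]+),([0-9]+)\\)", s)[[1]]
  gap_m <- gregexpr("\\[([0-9]+),([0-9]+)\\]", s)[[1]]
  boxes_raw <- regmatches(s, list(box_m))[[1]]
  gaps_raw <- if (gap_m[1] == -1L) character(0) else regmatches(s, list(gap_m))[[1]]
  if (length(boxes_raw) == 0L) stop("no boxes found in spec", call. = FALSE)
  if (length(gaps_raw) != length(boxes_raw) - 1L)
    stop("expected one [dmin,dmax] interval between each pair of boxes", call. = FALSE)
  num2 <- function(z) as.integer(strsplit(gsub("[][()]", "", z), ",", fixed = TRUE)[[1]])
  boxes <- do.call(rbind, lapply(boxes_raw, num2))
  colnames(boxes) <- c("length", "k")
  gaps <- if (length(gaps_raw)) do.call(rbind, lapply(gaps_raw, num2))
          else matrix(integer(0), 0, 2)
  colnames(gaps) <- c("dmin", "dmax")
  validate_motif_spec(boxes, gaps)
  list(boxes = boxes, gaps = gaps)
}

validate_motif_spec <- function(boxes, gaps) {
  if (any(boxes[, "k"] >= boxes[, "length"]) || any(boxes[, "length"] < 1L))
    stop("each box needs 0 <= k < length", call. = FALSE)
  if (nrow(gaps) && any(gaps[, "dmin"] > gaps[, "dmax"] | gaps[, "dmin"] < 0L))
    stop("each gap interval needs 0 <= dmin <= dmax", call. = FALSE)
  invisible(TRUE)
}

#' Structured motif extraction with quorum
#'
#' A structured motif is a tuple of `beta` boxes separated by spacers whose
#' lengths must fall in given intervals — the shape of composite
#' transcription-factor binding sites. A structured motif has a
#' `(k_i)`-occurrence in a sequence when each box `i` k_i-occurs there and
#' consecutive occurrences are separated by a spacer of `g` letters with
#' `dmin_i <= g <= dmax_i` (`g = start_{i+1} - end_i - 1`, the count of
#' letters strictly between the boxes). Candidates are strictly valid:
#' their boxes co-occur with zero errors and compliant spacers in at least
#' one source sequence.
#'
#' The extraction proceeds in three stages: (1) per box slot, factors
#' k_i-occurring in at least `quorum` sequences are found (a necessary
#' condition for any structured motif using that box); (2) candidate box
#' tuples are read off exact occurrence chains in the input sequences;
#' (3) each candidate is verified per sequence by an interval join over its
#' boxes' k_i-occurrence lists ([box_occurrences()]), and candidates
#' chaining in at least `quorum` sequences are reported.
#'
#' @param seqs character vector of N >= 2 sequences.
#' @param spec either a notation string accepted by [parse_motif_spec()] or
#'   a list with matrices `boxes` and `gaps` in that format. With a single
#'   box the call degenerates to [single_motif_extract()].
#' @param quorum minimum number of sequences with a full occurrence chain.
#' @param model `"hamming"` or `"edit"`.
#' @return A `data.frame` sorted by decreasing `quorum_count` then motif
#'   notation: `motif` (boxes joined by their `[dmin,dmax]` intervals),
#'   one `box1..boxB` column per box, `source_seq`, `quorum_count`, and a
#'   list column `seq_occurs` of per-sequence logicals.
#' @examples
#' seqs <- c("AAATCCC", "AAATTCCCG", "AAACCC")
#' structured_motif_extract(seqs, "(3,0)[1,2](3,0)", quorum = 2)
#' @export
structured_motif_extract <- function(seqs, spec, quorum,
                                     model = c("hamming", "edit")) {
  model <- match.arg(model)
  if (is.character(spec)) spec <- parse_motif_spec(spec)
  boxes <- spec$boxes
  gaps <- spec$gaps
  validate_motif_spec(boxes, gaps)
  beta <- nrow(boxes)
  seqs <- as_seqs(seqs)
  N <- length(seqs)
  if (N < 2L) stop("at least two sequences are required", call. = FALSE)
  quorum <- as.integer(quorum)
  if (quorum < 1L || quorum > N) stop("quorum must be in [1, N]", call. = FALSE)
  if (beta == 1L)
    return(single_motif_extract(seqs, boxes[1, "length"], boxes[1, "k"],
                                quorum, model))

  # stage 1: per-slot valid box strings (quorum is a necessary condition)
  slot_valid <- vector("list", beta)
  for (b in seq_len(beta)) {
    sm <- single_motif_extract(seqs, boxes[b, "length"], boxes[b, "k"],
                               quorum, model)
    slot_valid[[b]] <- sm$motif
    if (length(slot_valid[[b]]) == 0L) return(empty_structured_df(beta))
  }

  # stage 2: candidate tuples from exact chains in single source sequences
  cands <- list()
  for (si in seq_len(N)) {
    occ_by_slot <- lapply(seq_len(beta), function(b) {
      exact_occurrences(seqs[si], slot_valid[[b]])
    })
    chains <- chain_exact(occ_by_slot, gaps)
    for (ch in chains) {
      key <- paste(ch$strings, collapse = "|")
      if (is.null(cands[[key]]))
        cands[[key]] <- list(strings = ch$strings, source_seq = si)
    }
  }
  if (length(cands) == 0L) return(empty_structured_df(beta))

  # stage 3: verify candidates across all sequences by interval join
  notation <- apply(gaps, 1L, function(g) sprintf("[%d,%d]", g[1], g[2]))
  res <- lapply(cands, function(cd) {
    occs <- lapply(seq_len(beta), function(b) {
      box_occurrences(seqs, cd$strings[b], boxes[b, "k"], model)
    })
    ok <- vapply(seq_len(N), function(s) {
      has_chain(lapply(occs, `[[`, s), gaps)
    }, logical(1))
    motif <- paste0(cd$strings[1],
                    paste0(vapply(seq_len(beta - 1L), function(b)
                      paste0(notation[b], cd$strings[b + 1L]), character(1)),
                      collapse = ""))
    list(motif = motif, strings = cd$strings, source_seq = cd$source_seq,
         quorum_count = sum(ok), seq_occurs = ok)
  })
  out <- data.frame(motif = vapply(res, `[[`, character(1), "motif"),
                    stringsAsFactors = FALSE)
  for (b in seq_len(beta))
    out[[paste0("box", b)]] <- vapply(res, function(r) r$strings[b], character(1))
  out$source_seq <- vapply(res, function(r) as.integer(r$source_seq), integer(1))
  out$quorum_count <- vapply(res, function(r) as.integer(r$quorum_count), integer(1))
  out$seq_occurs <- I(unname(lapply(res, `[[`, "seq_occurs")))
  out <- out[out$quorum_count >= quorum, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_structured_df(beta))
  out <- out[order(-out$quorum_count, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_structured_df <- function(beta) {
  d <- data.frame(motif = character(0), stringsAsFactors = FALSE)
  for (b in seq_len(beta)) d[[paste0("box", b)]] <- character(0)
  d$source_seq <- integer(0)
  d$quorum_count <- integer(0)
  d$seq_occurs <- I(list())
  d
}

# all exact occurrences of any of `strings` in sequence s:
# data.frame(string, start, end), 0-based inclusive
exact_occurrences <- function(s, strings) {
  res <- lapply(strings, function(v) {
    # gregexpr skips overlapping occurrences; rescan manually
    starts <- integer(0)
    from <- 1L
    L <- nchar(v)
    repeat {
      p <- regexpr(v, substr(s, from, nchar(s)), fixed = TRUE)
      if (p == -1L) break
      st <- from + p - 1L
      starts <- c(starts, st)
      from <- st + 1L
    }
    if (length(starts) == 0L) return(NULL)
    data.frame(string = v, start = starts - 1L, end = starts + L - 2L,
               stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(data.frame(string = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

# enumerate distinct box-string tuples chainable through the gap intervals
chain_exact <- function(occ_by_slot, gaps) {
  beta <- length(occ_by_slot)
  partial <- lapply(seq_len(nrow(occ_by_slot[[1]])), function(r)
    list(strings = occ_by_slot[[1]]$string[r], end = occ_by_slot[[1]]$end[r]))
  for (b in seq_len(beta - 1L)) {
    nxt <- occ_by_slot[[b + 1L]]
    grown <- list()
    for (p in partial) {
      lo <- p$end + gaps[b, "dmin"] + 1L
      hi <- p$end + gaps[b, "dmax"] + 1L
      sel <- which(nxt$start >= lo & nxt$start <= hi)
      for (r in sel) {
        grown[[length(grown) + 1L]] <-
          list(strings = c(p$strings, nxt$string[r]), end = nxt$end[r])
      }
    }
    partial <- grown
    if (length(partial) == 0L) return(list())
  }
  # distinct tuples only
  keys <- vapply(partial, function(p) paste(p$strings, collapse = "|"), character(1))
  partial[!duplicated(keys)]
}

# does a chain of occurrences (one data.frame per slot, columns start/end)
# exist with every spacer length inside its interval?
has_chain <- function(occ_list, gaps) {
  reach <- occ_list[[1]]$end
  if (length(reach) == 0L) return(FALSE)
  for (b in seq_len(length(occ_list) - 1L)) {
    nxt <- occ_list[[b + 1L]]
    if (nrow(nxt) == 0L) return(FALSE)
    reach <- sort(unique(reach))
    ok <- vapply(seq_len(nrow(nxt)), function(r) {
      lo <- nxt$start[r] - gaps[b, "dmax"] - 1L
      hi <- nxt$start[r] - gaps[b, "dmin"] - 1L
      if (hi < reach[1]) return(FALSE)
      idx <- findInterval(hi, reach)
      idx >= 1L && reach[idx] >= lo
    }, logical(1))
    reach <- nxt$end[ok]
    if (length(reach) == 0L) return(FALSE)
  }
  TRUE
}
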