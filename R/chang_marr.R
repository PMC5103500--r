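#' De Bruijn sequences and q-gram ranking
#'
#' `debruijn_sequence()` builds the lexicographically least de Bruijn
#' sequence B(q, sigma): a circular string of length \eqn{\sigma^q} in which
#' every q-gram over the alphabet occurs exactly once, constructed by
#' Lyndon-word concatenation (the FKM algorithm) in time linear in the
#' output. `qgram_rank()` maps a q-gram to its 0-based base-\eqn{\sigma}
#' rank (leftmost letter most significant, letter order = alphabet order);
#' `qgram_unrank()` inverts it.
#'
#' A single-letter alphabet is degenerate: the sequence is that letter
#' repeated q times.
#'
#' @param q q-gram length (>= 1).
#' @param alphabet character vector of distinct single letters, in rank
#'   order.
#' @param s a q-gram string over `alphabet`.
#' @param rank 0-based rank in `[0, sigma^q)`.
#' @return `debruijn_sequence()` and `qgram_unrank()` return strings;
#'   `qgram_rank()` returns a 0-based integer rank.
#' @examples
#' debruijn_sequence(2, c("a", "b"))      # "aabb"
#' qgram_rank("AC", c("A", "C", "G", "T")) # 1
#' @export
debruijn_sequence <- function(q, alphabet) {
  q <- as.integer(q)
  alphabet <- check_alphabet(alphabet)
  sigma <- length(alphabet)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  if (sigma == 1L) return(paste(rep(alphabet, q), collapse = ""))
  # FKM: concatenate the Lyndon words over 0..sigma-1 whose length divides q
  a <- integer(q + 1L)            # a[2..q+1] hold the working word, 1-based
  out <- vector("list", 0L)
  db <- function(t, p) {
    if (t > q) {
      if (q %% p == 0L) out[[length(out) + 1L]] <<- a[2L:(p + 1L)]
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= sigma - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  paste(alphabet[unlist(out) + 1L], collapse = "")
}

check_alphabet <- function(alphabet) {
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 1L) stop("alphabet must be non-empty", call. = FALSE)
  if (any(nchar(alphabet) != 1L)) stop("alphabet entries must be single letters", call. = FALSE)
  if (anyDuplicated(alphabet)) stop("alphabet letters must be distinct", call. = FALSE)
  alphabet
}

#' @rdname debruijn_sequence
#' @export
qgram_rank <- function(s, alphabet) {
  alphabet <- check_alphabet(alphabet)
  letters_ <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(letters_, alphabet)
  if (anyNA(idx)) stop("q-gram contains letters outside the alphabet", call. = FALSE)
  sigma <- length(alphabet)
  r <- 0
  for (d in idx - 1L) r <- r * sigma + d
  as.integer(r)
}

#' @rdname debruijn_sequence
#' @export
qgram_unrank <- function(rank, q, alphabet) {
  alphabet <- check_alphabet(alphabet)
  sigma <- length(alphabet)
  rank <- as.integer(rank)
  if (rank < 0L || rank >= sigma^q) stop("rank out of range", call. = FALSE)
  digits <- integer(q)
  for (p in q:1) {
    digits[p] <- rank %% sigma
    rank <- rank %/% sigma
  }
  paste(alphabet[digits + 1L], collapse = "")
}

#' Chang-Marr q-gram distance index
#'
#' For every q-gram s over the alphabet, the index stores the minimal
#' distance between s and any factor of the pattern `x`; this array of
#' \eqn{\sigma^q} entries is the preprocessing behind average-case optimal
#' approximate matching. `build_cm_index()` computes it with a single FLASM
#' run: the linearised de Bruijn sequence (extended by its first q-1
#' letters so every circular q-gram is a linear factor) is the FLASM
#' pattern, `x` is the text, the factor length is q and the threshold is
#' q-1, the largest the core admits. A q-gram whose minimal distance
#' exceeds q-1 gets the value q: under Hamming a length-q window can always
#' be reached with q substitutions, and under the edit model the entry is
#' capped at q, which loses nothing for consumers that threshold below q.
#'
#' `build_cm_index_naive()` is the quadratic baseline and test oracle:
#' direct minimisation over every (q-gram, factor) pair — sliding-window
#' mismatch counts under Hamming, and under edit the minimum of
#' [utils::adist()] over all pattern factors whose length allows a distance
#' below q, capped at q.
#'
#' @param x pattern string to index.
#' @param q q-gram length, `1 <= q <= nchar(x)`.
#' @param alphabet ordered letter set (default DNA `A,C,G,T`); `x` must use
#'   only these letters.
#' @param model `"hamming"` or `"edit"`.
#' @return An object of class `cm_index`: a list with `alphabet`, `q`,
#'   `model` and the integer array `D` of length `sigma^q`, indexed by
#'   `qgram_rank(s, alphabet) + 1`.
#' @examples
#' idx <- build_cm_index("AAC", 2, alphabet = c("A", "C"))
#' idx$D  # AA, AC exact; CA, CC at distance 1
#' @export
build_cm_index <- function(x, q, alphabet = c("A", "C", "G", "T"),
                           model = c("hamming", "edit")) {
  model <- match.arg(model)
  alphabet <- toupper(check_alphabet(alphabet))
  x <- as_seq(x, "pattern")
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  if (q > nchar(x)) stop("q exceeds the pattern length", call. = FALSE)
  check_letters(x, alphabet)
  sigma <- length(alphabet)
  db <- debruijn_sequence(q, alphabet)
  lin <- if (q > 1L) paste0(db, substr(db, 1L, q - 1L)) else db
  prof <- flasm_profile(text = x, pattern = lin, factor_length = q,
                        max_distance = q - 1L, model = model)
  D <- rep(q, sigma^q)
  ends <- q:nchar(lin)  # 1-based ending positions of q-gram windows in lin
  for (i in ends) {
    gram <- substr(lin, i - q + 1L, i)
    r <- qgram_rank(gram, alphabet)
    e <- prof$min_e[i]          # 0-based end i-1 -> index i
    D[r + 1L] <- min(e, q)
  }
  new_cm_index(alphabet, q, model, as.integer(D))
}

new_cm_index <- function(alphabet, q, model, D) {
  structure(list(alphabet = alphabet, q = q, model = model, D = D),
            class = "cm_index")
}

check_letters <- function(x, alphabet) {
  ls <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  if (!all(ls %in% alphabet))
    stop("pattern contains letters outside the alphabet", call. = FALSE)
}

#' @rdname build_cm_index
#' @export
build_cm_index_naive <- function(x, q, alphabet = c("A", "C", "G", "T"),
                                 model = c("hamming", "edit")) {
  model <- match.arg(model)
  alphabet <- toupper(check_alphabet(alphabet))
  x <- as_seq(x, "pattern")
  q <- as.integer(q)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  if (q > nchar(x)) stop("q exceeds the pattern length", call. = FALSE)
  check_letters(x, alphabet)
  sigma <- length(alphabet)
  n_grams <- sigma^q
  grams <- vapply(0:(n_grams - 1L), qgram_unrank, character(1),
                  q = q, alphabet = alphabet)
  if (model == "hamming") {
    xc <- strsplit(x, "", fixed = TRUE)[[1]]
    starts <- seq_len(nchar(x) - q + 1L)
    fac <- t(vapply(starts, function(s) xc[s:(s + q - 1L)], character(q)))
    gm <- matrix(unlist(strsplit(grams, "", fixed = TRUE)),
                 nrow = n_grams, byrow = TRUE)
    acc <- matrix(0L, n_grams, length(starts))
    for (p in seq_len(q))
      acc <- acc + outer(gm[, p], fac[, p], "!=")
    D <- pmin(apply(acc, 1L, min), q)
  } else {
    # only factors with |length - q| < q can be closer than q
    m <- nchar(x)
    lens <- seq_len(2L * q - 1L)
    facs <- unique(unlist(lapply(lens, function(L) {
      if (L > m) return(character(0))
      st <- seq_len(m - L + 1L)
      substring(x, st, st + L - 1L)
    })))
    dm <- adist(grams, facs)
    D <- pmin(apply(dm, 1L, min), q)
  }
  new_cm_index(alphabet, q, model, as.integer(D))
}

#' @export
print.cm_index <- function(x, ...) {
  cat("<cm_index ", x$model, ", q=", x$q, ", sigma=", length(x$alphabet),
      ", ", length(x$D), " entries, ", sum(x$D == 0L), " exact>\n", sep = "")
  invisible(x)
}

#' Serialise a Chang-Marr index
#'
#' Writes a JSON header line (`# {...}` with alphabet, q and model) followed
#' by a two-column TSV of q-gram and minimal distance.
#'
#' @param index a `cm_index`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cm_index <- function(index, path) {
  stopifnot(inherits(index, "cm_index"))
  hdr <- paste0("# ", jsonlite::toJSON(
    list(alphabet = index$alphabet, q = index$q, model = index$model),
    auto_unbox = TRUE))
  grams <- vapply(seq_along(index$D) - 1L, qgram_unrank, character(1),
                  q = index$q, alphabet = index$alphabet)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "qgram\tdistance"), con)
  writeLines(paste(grams, index$D, sep = "\t"), con)
  invisible(path)
}
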