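#' String rotations and pattern doubling
#'
#' `rotate_string(x, r)` returns the r-th rotation
#' `x[r..m-1] x[0..r-1]` (0-based r, taken modulo the length).
#' `double_pattern(x)` concatenates `x` with its first `m - 1` letters; the
#' length-m factors of the result are exactly the m rotations of `x`, which
#' is what reduces circular matching to fixed-length matching.
#'
#' @param x a string.
#' @param r rotation index (any integer; reduced modulo `nchar(x)`).
#' @return a character string.
#' @examples
#' rotate_string("AAGATG", 2)  # "GATGAA"
#' double_pattern("AAGATG")    # "AAGATGAAGAT"
#' @export
rotate_string <- function(x, r) {
  x <- as_seq(x)
  m <- nchar(x)
  r <- as.integer(r) %% m
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, m), substr(x, 1L, r))
}

#' @rdname rotate_string
#' @export
double_pattern <- function(x) {
  x <- as_seq(x, "pattern")
  m <- nchar(x)
  if (m < 1L) stop("pattern must be non-empty", call. = FALSE)
  if (m == 1L) return(x)
  paste0(x, substr(x, 1L, m - 1L))
}

#' Approximate circular string matching
#'
#' Find all factors of `text` within `max_distance` of any rotation of
#' `pattern`. The pattern is doubled ([double_pattern()]) and the FLASM core
#' is run with the factor length set to the pattern length, so every
#' rotation is one pattern window; the method's cost is independent of
#' `max_distance`.
#'
#' Each returned tuple's `pattern_end` identifies a window of the doubled
#' pattern; the derived `rotation` column gives the rotation index
#' `(pattern_end - m + 1) mod m`. For periodic patterns, distinct windows
#' can spell the same rotation string; such duplicate `(text_end, distance)`
#' rows are retained unless `dedupe_rotations = TRUE`, which keeps the
#' smallest `pattern_end` per `(text_end, rotation string)`.
#'
#' @inheritParams flasm
#' @param dedupe_rotations drop duplicate rows that spell the same rotation
#'   string at the same text position (default `FALSE`).
#' @return A `data.frame` with columns `text_end`, `pattern_end`,
#'   `distance`, `rotation`.
#' @examples
#' acsm("CCGATGAACC", "AAGATG", 0)  # rotation GATGAA occurs at positions 2..7
#' @export
acsm <- function(text, pattern, max_distance, model = c("hamming", "edit"),
                 mode = c("all", "best"), dedupe_rotations = FALSE) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  text <- as_seq(text, "text")
  pattern <- as_seq(pattern, "pattern")
  m <- nchar(pattern)
  if (m > nchar(text)) stop("pattern longer than text", call. = FALSE)
  if (max_distance >= m) stop("max_distance must be smaller than the pattern length", call. = FALSE)
  res <- flasm(text, double_pattern(pattern), m, max_distance, model, mode)
  res$rotation <- (res$pattern_end - m + 1L) %% m
  if (dedupe_rotations && nrow(res) > 0L) {
    rot_str <- vapply(res$rotation, function(r) rotate_string(pattern, r), character(1))
    keep <- !duplicated(data.frame(res$text_end, rot_str))
    res <- res[keep, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}
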