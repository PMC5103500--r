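#' Fixed-length approximate string matching
#'
#' Find all factors of `text` that are within `max_distance` of any factor
#' of length `factor_length` of `pattern`, under the Hamming or the edit
#' distance model. Matches are reported as `<j, i, e>` tuples: 0-based
#' inclusive ending position `j` in the text, 0-based ending position `i`
#' of the pattern factor, and distance `e`.
#'
#' Under the Hamming model the reported distance is the mismatch count of
#' the two length-\eqn{\ell} windows ending at `j` and `i`. Under the edit
#' model the reported distance for a text ending position `j` is the
#' *minimum over start positions* of the edit distance between a text factor
#' ending at `j` and the pattern window (standard semi-global semantics), so
#' at most one tuple is reported per `(j, i)` pair, carrying the minimal
#' distance.
#'
#' Both models run in \eqn{O(m \lceil \ell/w \rceil n)} time, independent of
#' `max_distance` and of the alphabet. Sequences are uppercased on ingest;
#' beyond that any symbol (including `N` or gap characters) is an ordinary
#' letter that matches only itself. The pattern may be longer than the text
#' (the circular applications rely on this); the factor length must not
#' exceed either string.
#'
#' @param text text string to search (length n).
#' @param pattern pattern string whose fixed-length factors are matched
#'   (length m).
#' @param factor_length factor length \eqn{\ell}, `1 <= factor_length <=
#'   min(n, m)`.
#' @param max_distance distance threshold k, `0 <= max_distance <
#'   factor_length`. `k = 0` performs exact fixed-length matching.
#' @param model `"hamming"` or `"edit"`.
#' @param mode `"all"` reports every admissible tuple; `"best"` reports the
#'   single tuple minimising `(distance, text_end, pattern_end)`
#'   lexicographically (zero rows if nothing is within `max_distance`).
#'
#' @return A `data.frame` with integer columns `text_end`, `pattern_end`,
#'   `distance`, sorted by `(text_end, pattern_end)`.
#'
#' @examples
#' # factors of length 3 of AAGATG are AAG, AGA, GAT, ATG; two match exactly
#' flasm("ATGGCAAGT", "AAGATG", 3, 0)
#' # one substitution also pairs AGA with AGT
#' flasm("ATGGCAAGT", "AAGATG", 3, 1)
#' @seealso [acsm()], [single_motif_extract()], [build_cm_index()]
#' @export
flasm <- function(text, pattern, factor_length, max_distance,
                  model = c("hamming", "edit"), mode = c("all", "best")) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  text <- as_seq(text, "text")
  pattern <- as_seq(pattern, "pattern")
  p <- check_flasm_params(text, pattern, factor_length, max_distance)
  res <- cpp_flasm(text, pattern, p$ell, p$k,
                   if (model == "hamming") 0L else 1L, mode == "best")
  attr(res, "flasm") <- list(model = model, factor_length = p$ell,
                             max_distance = p$k, mode = mode)
  res
}

check_flasm_params <- function(text, pattern, factor_length, max_distance) {
  n <- nchar(text); m <- nchar(pattern)
  ell <- as.integer(factor_length); k <- as.integer(max_distance)
  if (n < 1L || m < 1L) stop("text and pattern must be non-empty", call. = FALSE)
  if (is.na(ell) || ell < 1L) stop("factor_length must be a positive integer", call. = FALSE)
  if (ell > m) stop("factor_length exceeds the pattern length", call. = FALSE)
  if (ell > n) stop("factor_length exceeds the text length", call. = FALSE)
  if (is.na(k) || k < 0L) stop("max_distance must be a non-negative integer", call. = FALSE)
  if (k >= ell) stop("max_distance must be smaller than factor_length", call. = FALSE)
  list(ell = ell, k = k)
}

# Per-pattern-ending-position summary: minimal distance over all text
# positions and count of text positions within k. Internal workhorse for
# motif extraction and the Chang-Marr index.
flasm_profile <- function(text, pattern, factor_length, max_distance,
                          model = c("hamming", "edit")) {
  model <- match.arg(model)
  text <- as_seq(text, "text")
  pattern <- as_seq(pattern, "pattern")
  p <- check_flasm_params(text, pattern, factor_length, max_distance)
  cpp_flasm_profile(text, pattern, p$ell, p$k,
                    if (model == "hamming") 0L else 1L)
}
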