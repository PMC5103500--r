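#' Fixed-width bit vectors
#'
#' A `bitrow` is an \eqn{\ell}-bit vector with truncating left shift,
#' carry-propagating addition modulo \eqn{2^\ell}, boolean operations and
#' population count. It is the state container shared by both FLASM cores:
#' bit 0 (stored first) is the least significant bit, i.e. the most recent
#' alignment column, so shifting in the newest mismatch bit is a left shift.
#' All operations truncate to the row's width, which may exceed the machine
#' word; internally bits are packed into words of [flasm_word_size()] bits
#' and the word-level kernels are the same ones the matching cores use.
#'
#' @param ell positive integer width in bits.
#' @param bits integer vector of 0/1 digits, bit 0 first.
#' @param r,a,b `bitrow` objects (equal widths where two are taken).
#' @param p bit position in `[0, ell)`.
#'
#' @return `bitrow()`, `bitrow_zero()`, `bitrow_ones()` and the operation
#'   functions return `bitrow` objects; `bitrow_popcount()` and
#'   `bitrow_get()` return integers.
#'
#' @examples
#' r <- bitrow(c(1, 1, 0))          # value 3 at width 3
#' bitrow_shl(r)                    # value 6
#' bitrow_popcount(bitrow_ones(70)) # 70
#' @name bitrow
NULL

new_bitrow <- function(bits) {
  structure(as.integer(bits), class = "bitrow")
}

#' @rdname bitrow
#' @export
bitrow <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) < 1L || anyNA(bits) || any(bits < 0L | bits > 1L))
    stop("bits must be a non-empty vector of 0/1 digits", call. = FALSE)
  new_bitrow(bits)
}

#' @rdname bitrow
#' @export
bitrow_zero <- function(ell) {
  stopifnot(ell >= 1)
  new_bitrow(integer(ell))
}

#' @rdname bitrow
#' @export
bitrow_ones <- function(ell) {
  stopifnot(ell >= 1)
  new_bitrow(rep(1L, ell))
}

#' @rdname bitrow
#' @export
bitrow_width <- function(r) length(unclass(r))

check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("bitrow widths differ", call. = FALSE)
}

#' @rdname bitrow
#' @export
bitrow_shl <- function(r) new_bitrow(cpp_bv_shl1(unclass(r)))

#' @rdname bitrow
#' @export
bitrow_add <- function(a, b) {
  check_pair(a, b)
  new_bitrow(cpp_bv_add(unclass(a), unclass(b)))
}

#' @rdname bitrow
#' @export
bitrow_popcount <- function(r) cpp_bv_popcount(unclass(r))

#' @rdname bitrow
#' @export
bitrow_and <- function(a, b) { check_pair(a, b); new_bitrow(cpp_bv_bitop(unclass(a), unclass(b), 0L)) }

#' @rdname bitrow
#' @export
bitrow_or <- function(a, b) { check_pair(a, b); new_bitrow(cpp_bv_bitop(unclass(a), unclass(b), 1L)) }

#' @rdname bitrow
#' @export
bitrow_xor <- function(a, b) { check_pair(a, b); new_bitrow(cpp_bv_bitop(unclass(a), unclass(b), 2L)) }

#' @rdname bitrow
#' @export
bitrow_not <- function(r) new_bitrow(cpp_bv_not(unclass(r)))

#' @rdname bitrow
#' @export
bitrow_get <- function(r, p) {
  ell <- bitrow_width(r)
  if (p < 0 || p >= ell) stop("bit position out of range", call. = FALSE)
  unclass(r)[p + 1L]
}

#' @export
print.bitrow <- function(x, ...) {
  cat("<bitrow ", length(unclass(x)), " bits: ",
      paste(rev(unclass(x)), collapse = ""), ">\n", sep = "")
  invisible(x)
}

#' Machine word size used by the bit-vector kernels
#'
#' The number of bits packed per word in the multi-word bit vectors; drives
#' the \eqn{\lceil \ell/w \rceil} factor of the cores' run time. Exposed
#' read-only for complexity-scaling checks; correctness never depends on it.
#'
#' @return integer, the word size in bits.
#' @export
flasm_word_size <- function() cpp_word_size()
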