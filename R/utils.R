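# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# one string in, uppercased; sequences are treated as raw symbols thereafter
as_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  toupper(x)
}

as_seqs <- function(x) {
  x <- vapply(x, as_seq, character(1))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- paste0("seq", seq_along(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
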