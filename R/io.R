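#' Read and write FASTA / MultiFASTA
#'
#' `read_fasta()` parses a (Multi)FASTA file via Biostrings, accepting
#' multi-line records, CRLF line endings and lowercase letters (sequences
#' are uppercased on ingest). Record ids are the first whitespace-delimited
#' token of each header. Malformed files fail with the offending line
#' number; empty sequences and duplicate ids are rejected.
#' `write_fasta()` writes records wrapped at 60 columns.
#'
#' @param path file path.
#' @param records named character vector of sequences.
#' @return `read_fasta()` a named character vector; `write_fasta()` the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  first <- nonempty[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA: expected '>' header at line ", first, call. = FALSE)
  bad <- grep("^>$|^>\\s", lines)
  if (length(bad))
    stop("malformed FASTA: empty record id at line ", bad[1], call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[anyDuplicated(ids)], call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record: ", ids[which(!nzchar(seqs))[1]],
         call. = FALSE)
  names(seqs) <- ids
  seqs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  records <- as_seqs(records)
  set <- Biostrings::BStringSet(records)
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write a result table with a metadata header
#'
#' Serialises a match table (or any data.frame) as TSV preceded by
#' `#`-prefixed `key: value` metadata lines — enough to re-run the command
#' that produced it. List columns are flattened to comma-separated fields.
#' `read_results()` reads the table back, ignoring the metadata.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param meta named list of metadata values.
#' @return the path (write) / a data.frame (read), invisibly for write.
#' @export
write_results <- function(table, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, paste(meta[[key]], collapse = ",")), con)
  flat <- table
  for (cn in names(flat)) {
    if (is.list(flat[[cn]]))
      flat[[cn]] <- vapply(flat[[cn]], function(v)
        paste(as.vector(v), collapse = ","), character(1))
  }
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

result_meta <- function(..., seed = NULL) {
  meta <- list(...)
  meta$seed <- seed
  meta$package <- paste0("flasmr ", as.character(utils::packageVersion("flasmr")))
  meta$coordinates <- "0-based inclusive ending positions"
  meta[!vapply(meta, is.null, logical(1))]
}
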