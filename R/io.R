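#' Read a FASTQ file into a tibble of reads
#'
#' Minimal strict FASTQ reader (plain or gzip). Each record must be four
#' lines: `@id`, sequence, `+`, quality of matching length. A malformed
#' record raises an error naming the record index.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  con <- gzfile(path, "r")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble(read_id = character(), seq = character(),
                  qual = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf(
      "malformed FASTQ record %d in %s: truncated record",
      length(lines) %/% 4L + 1L, path
    ))
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ record %d in %s", bad[1L], path))
  }
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    seq = toupper(seqs), qual = qual
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `read_id` and `seq` (and optionally
#'   `qual`; a constant high quality is used otherwise).
#' @param path Output path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(out, con)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that return/accept plain named character
#' vectors, the representation the rest of the package uses.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(unname(seqs)), nm), path
  )
  invisible(path)
}
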