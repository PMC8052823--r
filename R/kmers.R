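#' Canonicalise k-mers
#'
#' Maps each k-mer to the lexicographic minimum of itself and its reverse
#' complement, merging the two strands of a locus onto a single key. The
#' map is a projection: `canonicalize(canonicalize(x))` equals
#' `canonicalize(x)`.
#'
#' @param x Character vector of ACGT k-mers.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalize(c("AAACC", "TTTTT"))
#' @export
canonicalize <- function(x) {
  rc <- revcomp(x)
  swap <- rc < x
  x[swap] <- rc[swap]
  x
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != round(k) ||
      k < 3 || k > 63) {
    abort("`k` must be a single integer between 3 and 63")
  }
  as.integer(k)
}

#' Decompose one read into its constituent k-mers
#'
#' Emits one k-mer per window start (`nchar(seq) - k + 1` windows).
#' Windows containing a non-ACGT character (for instance `N`) are skipped
#' and tallied in the `skipped` attribute of the result. Reads shorter
#' than `k` yield an empty vector.
#'
#' @param seq A single read sequence (character scalar).
#' @param k k-mer length (3 to 63).
#' @param canonical Merge strands by canonicalising each window?
#' @return Character vector of k-mers with attribute `skipped`, the number
#'   of windows dropped because they contained non-ACGT characters.
#' @examples
#' decompose_read("ACGTNACGT", k = 4)
#' @export
decompose_read <- function(seq, k, canonical = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  k <- check_k(k)
  n <- nchar(seq)
  if (n < k) {
    return(structure(character(0), skipped = 0L))
  }
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  ok <- !stringr::str_detect(kmers, "[^ACGT]")
  kmers <- kmers[ok]
  if (canonical && length(kmers)) kmers <- canonicalize(kmers)
  structure(kmers, skipped = sum(!ok))
}

new_kmer_tbl <- function(tbl, k, total_kmers, total_read_bases, n_skipped,
                         canonical, library_id = NA_character_,
                         sample_id = NA_character_) {
  structure(
    tbl,
    k = as.integer(k),
    total_kmers = as.numeric(total_kmers),
    total_read_bases = as.numeric(total_read_bases),
    n_skipped = as.numeric(n_skipped),
    canonical = isTRUE(canonical),
    library_id = library_id,
    sample_id = sample_id,
    class = c("kmer_tbl", class(tibble()))
  )
}

#' Count k-mers in a set of reads or sequences
#'
#' Decomposes every sequence into its k-length windows and tallies them
#' (canonically by default). Counting is exact and order-invariant;
#' windows containing non-ACGT characters are skipped and tallied.
#'
#' @param reads A tibble/data frame with a `seq` column (as produced by
#'   [read_fastq()] or [simulate_reads()]) or a character vector of
#'   sequences.
#' @param k k-mer length (3 to 63). The workflow default pair is
#'   `k = 15` (fast) and `k = 31` (high specificity).
#' @param canonical Merge strands (lexicographic minimum of each window
#'   and its reverse complement)? Strand-specific counting is available
#'   with `canonical = FALSE` for sensitivity analysis.
#' @param library_id,sample_id Optional identifiers recorded as
#'   attributes on the returned table.
#' @return A `kmer_tbl`: a tibble with columns `kmer` and `count`, sorted
#'   by k-mer, carrying attributes `k`, `total_kmers`, `total_read_bases`,
#'   `n_skipped`, `canonical`, `library_id` and `sample_id`.
#' @examples
#' count_kmers(c("ACGTACGT", "ACGTACGT"), k = 4)
#' @export
count_kmers <- function(reads, k, canonical = TRUE,
                        library_id = NA_character_,
                        sample_id = NA_character_) {
  k <- check_k(k)
  seqs <- if (is.data.frame(reads)) {
    if (!"seq" %in% names(reads)) abort("`reads` must have a `seq` column")
    as.character(reads$seq)
  } else {
    as.character(reads)
  }
  res <- cpp_count_kmers(seqs, k, isTRUE(canonical))
  tbl <- tibble(kmer = res$kmer, count = res$count) |> arrange(.data$kmer)
  new_kmer_tbl(tbl, k,
    total_kmers = res$total_kmers,
    total_read_bases = res$total_bases,
    n_skipped = res$skipped,
    canonical = canonical,
    library_id = library_id, sample_id = sample_id
  )
}

#' Count k-mers in one sequencing library (FASTQ)
#'
#' Reads a FASTQ file (optionally gzip-compressed) and aggregates k-mer
#' counts over all its reads.
#'
#' @param path Path to a FASTQ file, or an already-read tibble of reads.
#' @inheritParams count_kmers
#' @return A `kmer_tbl` (see [count_kmers()]).
#' @export
count_library <- function(path, k, canonical = TRUE,
                          library_id = NULL, sample_id = NA_character_) {
  reads <- if (is.data.frame(path)) path else read_fastq(path)
  if (is.null(library_id)) {
    library_id <- if (is.character(path)) basename(path) else NA_character_
  }
  count_kmers(reads, k,
    canonical = canonical,
    library_id = library_id, sample_id = sample_id
  )
}

#' Count k-mers in a reference genome (FASTA or sequences)
#'
#' Convenience wrapper for building the reference-side table used to
#' select single-copy k-mers for the GC model.
#'
#' @param x Path to a FASTA file or a character vector of sequences.
#' @inheritParams count_kmers
#' @return A `kmer_tbl`.
#' @export
count_reference_kmers <- function(x, k, canonical = TRUE) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fasta(x)
  } else {
    x
  }
  count_kmers(unname(seqs), k, canonical = canonical)
}

#' Define a satellite consensus sequence
#'
#' @param name Short name, e.g. `"minor"` (120 bp unit) or `"major"`
#'   (234 bp unit).
#' @param sequence ACGT consensus string of length L.
#' @param circular Treat the consensus as a circular unit (a tandem array
#'   makes the junction between adjacent units real sequence)? Default
#'   `TRUE`.
#' @return A `satellite_consensus` object (list with `name`, `sequence`,
#'   `L`, `circular`).
#' @export
satellite_consensus <- function(name, sequence, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  stri_check_acgt(sequence, "sequence")
  structure(
    list(name = name, sequence = sequence, L = nchar(sequence),
         circular = isTRUE(circular)),
    class = "satellite_consensus"
  )
}

#' @export
print.satellite_consensus <- function(x, ...) {
  cat(sprintf(
    "<satellite_consensus> %s: %d bp, %s\n", x$name, x$L,
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Decompose a satellite consensus into its constituent k-mers
#'
#' With `circular = TRUE` (the tandem-array reading) windows wrap across
#' the unit junction and the set has exactly L entries, one per start
#' position; a linear decomposition has `L - k + 1`. Duplicate canonical
#' k-mers (possible when the unit has internal periodicity) are flagged:
#' downstream frequency queries count each distinct canonical k-mer once.
#'
#' @param consensus A [satellite_consensus()] (or a plain ACGT string).
#' @param k k-mer length; must be smaller than the unit length L.
#' @param circular Override the consensus object's circularity.
#' @return A tibble with columns `start` (1-based on the consensus),
#'   `kmer` (forward-strand window), `canonical` and `is_duplicate`,
#'   carrying attributes `name`, `k`, `L`, `circular`.
#' @examples
#' cons <- satellite_consensus("toy", "ACGACGACG")
#' consensus_kmer_set(cons, k = 4)
#' @export
consensus_kmer_set <- function(consensus, k, circular = NULL) {
  if (is.character(consensus)) {
    consensus <- satellite_consensus("consensus", consensus)
  }
  stopifnot(inherits(consensus, "satellite_consensus"))
  k <- check_k(k)
  L <- consensus$L
  if (L <= k) abort(sprintf("unit length L = %d must exceed k = %d", L, k))
  circular <- circular %||% consensus$circular
  seq2 <- if (circular) {
    paste0(consensus$sequence, substr(consensus$sequence, 1L, k - 1L))
  } else {
    consensus$sequence
  }
  starts <- seq_len(if (circular) L else L - k + 1L)
  kmer <- substring(seq2, starts, starts + k - 1L)
  canonical <- canonicalize(kmer)
  structure(
    tibble(
      start = starts, kmer = kmer, canonical = canonical,
      is_duplicate = duplicated(canonical)
    ),
    name = consensus$name, k = k, L = L, circular = circular,
    class = c("consensus_kmer_set", class(tibble()))
  )
}

#' Write / read a k-mer table as sorted TSV with a JSON sidecar
#'
#' The TSV has two columns (`kmer`, `count`), sorted by k-mer; totals and
#' metadata go to `<path>.json`.
#'
#' @param x A `kmer_tbl`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a `kmer_tbl` (reader).
#' @export
write_kmer_tbl <- function(x, path) {
  stopifnot(inherits(x, "kmer_tbl"))
  readr::write_tsv(as_tibble(x), path)
  meta <- attributes(x)[c(
    "k", "total_kmers", "total_read_bases", "n_skipped",
    "canonical", "library_id", "sample_id"
  )]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kmer_tbl
#' @export
read_kmer_tbl <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_kmer_tbl(tbl, meta$k, meta$total_kmers, meta$total_read_bases,
               meta$n_skipped, meta$canonical, meta$library_id,
               meta$sample_id)
}
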