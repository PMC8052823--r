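#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the ACGT alphabet.
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAAC"))
#' @export
revcomp <- function(x) {
  stri_check_acgt(x)
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

# Error (naming the position of the first offending character) unless
# every string is pure ACGT.
stri_check_acgt <- function(x, arg = "x") {
  bad <- stringr::str_locate(x, "[^ACGT]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    abort(sprintf(
      "`%s` contains a non-ACGT character at string %d, position %d ('%s')",
      arg, i, bad[i], substr(x[i], bad[i], bad[i])
    ))
  }
  invisible(x)
}

# GC count (integer number of G/C characters) per string.
gc_count <- function(x) {
  stringr::str_count(x, "[GC]")
}

# Fraction of G/C characters per string.
gc_fraction <- function(x) {
  gc_count(x) / nchar(x)
}

# Derive a reproducible child seed from a base seed and a stream label,
# kept below 2^31 so it is a valid R integer.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
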