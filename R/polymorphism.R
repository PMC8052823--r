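#' Hamming distance between equal-length strings
#'
#' Substitution-only distance (indels are outside the workflow's model of
#' satellite polymorphism). Vectorised over pairs.
#'
#' @param a,b Character vectors; `nchar(a)` must equal `nchar(b)`
#'   elementwise.
#' @return Integer vector of mismatch counts.
#' @examples
#' hamming("AAAA", "TTTT")
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have the same length")
  }
  if (any(nchar(a) != nchar(b))) {
    abort("paired strings must have equal length")
  }
  out <- integer(length(a))
  for (len in unique(nchar(a))) {
    idx <- which(nchar(a) == len)
    ma <- seq_char_matrix(a[idx])
    mb <- seq_char_matrix(b[idx])
    out[idx] <- colSums(ma != mb)
  }
  out
}

#' Enumerate the Hamming neighborhood of a k-mer
#'
#' All sequences within Hamming distance `h` of `kmer` (the k-mer itself
#' included). The neighborhood size is `sum_{i<=h} choose(k, i) * 3^i`,
#' e.g. 991 for k = 15, h = 2. Only practical for small k and h; the
#' polymorphism matrix never enumerates neighborhoods (it scans observed
#' k-mers against consensus windows instead).
#'
#' @param kmer A single ACGT string.
#' @param h Maximum Hamming distance.
#' @return Character vector of distinct neighbors.
#' @export
hamming_neighborhood <- function(kmer, h) {
  stri_check_acgt(kmer, "kmer")
  k <- nchar(kmer)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(kmer, "")[[1L]]
  out <- kmer
  for (i in seq_len(h)) {
    pos_sets <- utils::combn(k, i, simplify = FALSE)
    for (ps in pos_sets) {
      alts <- lapply(ps, function(p) setdiff(bases, chars[p]))
      grid <- expand.grid(alts, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        x <- chars
        x[ps] <- as.character(grid[r, ])
        out <- c(out, paste(x, collapse = ""))
      }
    }
  }
  unique(out)
}

default_h_max <- function(k, h_max = NULL) {
  if (!is.null(h_max)) return(as.integer(h_max))
  if (k == 15L) return(2L)
  if (k == 31L) return(5L)
  abort("no default `h_max` for this k; supply it explicitly (2 for k = 15, 5 for k = 31)")
}

# Lossless pigeonhole prefilter: a k-mer within Hamming distance h of a
# consensus window must carry at least one of its h+1 disjoint blocks
# (length floor(k / (h+1))) as an exact substring of the circular
# consensus or its reverse complement.
pigeonhole_filter <- function(kmers, cks, h_max) {
  k <- attr(cks, "k")
  L <- attr(cks, "L")
  s <- k %/% (h_max + 1L)
  if (s < 3L || !attr(cks, "circular")) return(rep(TRUE, length(kmers)))
  unit <- paste(substr(cks$kmer, 1L, 1L), collapse = "")
  circ <- paste0(unit, substr(unit, 1L, s - 1L))
  seeds <- substring(circ, seq_len(L), seq_len(L) + s - 1L)
  seeds <- unique(c(seeds, revcomp(seeds)))
  keep <- rep(FALSE, length(kmers))
  for (b in seq_len(h_max + 1L)) {
    off <- (b - 1L) * s + 1L
    keep <- keep | substring(kmers, off, off + s - 1L) %in% seeds
  }
  keep
}

#' Match observed k-mers to consensus windows within a relaxed distance
#'
#' Computes the Hamming distance from each observed k-mer to every window
#' of the consensus decomposition — both the window and its reverse
#' complement, taking the smaller and recording the orientation. k-mers
#' whose minimum distance is at most `h_max` are matched; all
#' (position, orientation) pairs achieving the minimum are returned with
#' equal weight shares summing to one per k-mer.
#'
#' @param kmers Character vector of observed (canonical) k-mers.
#' @param cks A [consensus_kmer_set()].
#' @param h_max Maximum Hamming distance (default 2 for k = 15, 5 for
#'   k = 31).
#' @param prefilter Apply the lossless pigeonhole seed prefilter before
#'   the exact distance scan (a pure speedup)?
#' @return Tibble with columns `kmer`, `distance`, `start`, `orientation`
#'   (`+`/`-` relative to the consensus strand) and `weight`.
#' @export
match_relaxed <- function(kmers, cks, h_max = NULL, prefilter = TRUE) {
  stopifnot(inherits(cks, "consensus_kmer_set"))
  k <- attr(cks, "k")
  h_max <- default_h_max(k, h_max)
  if (length(kmers) && !all(nchar(kmers) == k)) {
    abort(sprintf("observed k-mers must have length k = %d", k))
  }
  empty <- tibble(kmer = character(), distance = integer(),
                  start = integer(), orientation = character(),
                  weight = numeric())
  if (!length(kmers)) return(empty)
  cand <- if (prefilter) kmers[pigeonhole_filter(kmers, cks, h_max)] else kmers
  if (!length(cand)) return(empty)
  d_f <- cpp_hamming_matrix(cand, cks$kmer)
  d_r <- cpp_hamming_matrix(cand, revcomp(cks$kmer))
  best <- pmin(apply(d_f, 1L, min), apply(d_r, 1L, min))
  hit <- which(best <= h_max)
  if (!length(hit)) return(empty)
  rows <- list()
  for (orient in c("+", "-")) {
    d <- if (orient == "+") d_f else d_r
    w <- which(d[hit, , drop = FALSE] == best[hit], arr.ind = TRUE)
    if (nrow(w)) {
      rows[[orient]] <- tibble(
        kmer = cand[hit[w[, 1L]]],
        distance = best[hit[w[, 1L]]],
        start = cks$start[w[, 2L]],
        orientation = orient
      )
    }
  }
  out <- bind_rows(rows)
  out |>
    group_by(.data$kmer) |>
    mutate(weight = 1 / n()) |>
    ungroup() |>
    arrange(.data$kmer, .data$start, .data$orientation)
}

#' Build the positional polymorphism matrix of a satellite consensus
#'
#' Scans the distinct observed k-mers of a library against the consensus
#' windows (never enumerating Hamming neighborhoods, which is infeasible
#' at k = 31, h = 5), keeps those within `h_max` mismatches, and spreads
#' each matched k-mer's frequency over the consensus positions it covers:
#' for every covered position, the frequency times the k-mer's weight
#' share is added to the row of the nucleotide the k-mer carries there
#' (after orienting the k-mer to the consensus strand). Columns are then
#' normalised to relative probabilities summing to one, giving a 4 x L
#' matrix; the per-position non-consensus fraction is
#' `1 - P(consensus base)`.
#'
#' @param counts A `kmer_tbl` (frequencies taken from `count`) or
#'   `norm_profile` (taken from `raw`).
#' @param cks A [consensus_kmer_set()] for the satellite.
#' @inheritParams match_relaxed
#' @return A `poly_matrix`: tibble with columns `position`, `A`, `C`,
#'   `G`, `T` (relative probabilities), `consensus_base`, `nonconsensus`,
#'   `support` (total frequency weight); attributes `satellite`, `L`,
#'   `k`, `h_max`.
#' @export
build_polymorphism_matrix <- function(counts, cks, h_max = NULL,
                                      prefilter = TRUE) {
  stopifnot(inherits(cks, "consensus_kmer_set"))
  k <- attr(cks, "k")
  L <- attr(cks, "L")
  circular <- attr(cks, "circular")
  h_max <- default_h_max(k, h_max)
  if (inherits(counts, "norm_profile")) {
    obs <- tibble(kmer = counts$kmer, freq = counts$raw)
  } else if (is.data.frame(counts) && all(c("kmer", "count") %in%
                                          names(counts))) {
    if (!is.null(attr(counts, "k")) && !identical(attr(counts, "k"), k)) {
      abort("`counts` and `cks` were built with different k")
    }
    obs <- tibble(kmer = counts$kmer, freq = counts$count)
  } else {
    abort("`counts` must be a kmer_tbl or norm_profile")
  }
  obs <- filter(obs, .data$freq > 0)
  matches <- match_relaxed(obs$kmer, cks, h_max, prefilter = prefilter)
  unit <- paste(substr(cks$kmer, 1L, 1L), collapse = "")
  if (!circular) unit <- substr(unit, 1L, L)  # cks kmer starts cover 1..L
  cons_chars <- strsplit(unit, "")[[1L]][seq_len(L)]

  if (nrow(matches) == 0L) {
    warn("no observed k-mers matched the consensus within h_max")
    out <- tibble(
      position = seq_len(L), A = NA_real_, C = NA_real_, G = NA_real_,
      T = NA_real_, consensus_base = cons_chars,
      nonconsensus = NA_real_, support = 0
    )
    return(structure(out, satellite = attr(cks, "name"), L = L, k = k,
                     h_max = h_max,
                     class = c("poly_matrix", class(tibble()))))
  }

  matches <- left_join(matches, obs, by = "kmer")
  oriented <- ifelse(matches$orientation == "+", matches$kmer,
                     revcomp(matches$kmer))
  base_mat <- seq_char_matrix(oriented)            # k x m
  m <- nrow(matches)
  pos_mat <- outer(0:(k - 1L), matches$start - 1L, `+`)
  pos_mat <- if (circular) pos_mat %% L + 1L else pos_mat + 1L
  contrib <- tibble(
    position = as.vector(pos_mat),
    base = as.vector(base_mat),
    w = rep(matches$freq * matches$weight, each = k)
  ) |>
    filter(.data$position <= L) |>
    group_by(.data$position, .data$base) |>
    summarise(w = sum(.data$w), .groups = "drop")

  wide <- tidyr::pivot_wider(contrib, names_from = "base",
                             values_from = "w", values_fill = 0)
  for (b in c("A", "C", "G", "T")) if (!b %in% names(wide)) wide[[b]] <- 0
  wide <- wide[, c("position", "A", "C", "G", "T")]
  full <- left_join(tibble(position = seq_len(L)), wide, by = "position")
  probs <- as.matrix(full[, c("A", "C", "G", "T")])
  probs[is.na(probs)] <- 0
  support <- rowSums(probs)
  rel <- probs / ifelse(support > 0, support, NA_real_)
  cons_prob <- rel[cbind(seq_len(L),
                         match(cons_chars, c("A", "C", "G", "T")))]
  out <- tibble(
    position = seq_len(L),
    A = rel[, "A"], C = rel[, "C"], G = rel[, "G"], T = rel[, "T"],
    consensus_base = cons_chars,
    nonconsensus = 1 - cons_prob,
    support = support
  )
  structure(out, satellite = attr(cks, "name"), L = L, k = k, h_max = h_max,
            class = c("poly_matrix", class(tibble())))
}

#' Positions with elevated non-consensus nucleotide usage
#'
#' @param matrix A `poly_matrix`.
#' @param threshold Minimum non-consensus fraction (default 0.20).
#' @return Integer vector of 1-based consensus positions.
#' @export
variable_sites <- function(matrix, threshold = 0.20) {
  stopifnot(inherits(matrix, "poly_matrix"))
  matrix$position[!is.na(matrix$nonconsensus) &
                    matrix$nonconsensus >= threshold]
}

#' Per-position report for a consensus window (e.g. the CENP-B box)
#'
#' Extracts nucleotide probabilities and non-consensus fractions for a
#' 1-based inclusive window of the consensus. The default window 62-78 is
#' the CENP-B binding motif of the mouse minor satellite; positions 75
#' and 78 (within the motif) and 79 (immediately adjacent) are flagged by
#' default because they are hotspots of nucleotide variability, position
#' 75 being critical for CENP-B binding.
#'
#' @param matrix A `poly_matrix`.
#' @param start,end Window bounds (1-based, inclusive).
#' @param flag_positions Positions to flag when inside the window.
#' @return The window's rows of the matrix plus a logical `flagged`
#'   column.
#' @export
motif_report <- function(matrix, start = 62, end = 78,
                         flag_positions = c(75, 78, 79)) {
  stopifnot(inherits(matrix, "poly_matrix"))
  L <- attr(matrix, "L")
  if (start < 1 || end > L || start > end) {
    abort(sprintf("window [%d, %d] out of range for L = %d", start, end, L))
  }
  out <- matrix[matrix$position >= start & matrix$position <= end, ]
  out$flagged <- out$position %in% flag_positions
  out
}
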