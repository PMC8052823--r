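# Character matrix (positions x reads) from equal-length sequences.
seq_char_matrix <- function(seqs) {
  if (!length(seqs)) return(matrix(character(0), nrow = 0, ncol = 0))
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = nchar(seqs[1L]))
}

# Best ungapped hit of every read against a consensus tile over starts
# 1..n_pos (leftmost minimum-mismatch position; compiled scan).
scan_tile <- function(seqs, tile, n_pos) {
  m <- cpp_scan_reads(seqs, tile, n_pos)
  list(mismatches = m[, 1L], start = m[, 2L])
}

#' Map reads onto satellite consensus sequences
#'
#' Ungapped best-hit scan of each read and its reverse complement against
#' the (circularised) consensus of each satellite, replacing an external
#' aligner. Gapped alignment is deliberately not attempted: the diversity
#' index counts substitution differences, and the workflow ignores the
#' contribution of indels. The reported strand is the read's orientation
#' relative to the consensus, and `start` is 1-based on the consensus
#' unit (modulo L for circular units). Ties among start positions break
#' leftmost; a read whose best identity ties between two satellites is
#' ambiguous and dropped; strand ties on one satellite resolve to `+`.
#'
#' @param reads Tibble with `read_id` and `seq` (or a character vector of
#'   sequences). Reads longer than 2L are scanned on their first 2L
#'   bases.
#' @param consensuses A [satellite_consensus()] or list of them.
#' @param min_identity Minimum identity (matches / aligned span) for a
#'   hit; hits below it are unmapped. Default 0.8.
#' @return Tibble of mapped reads: `read_id`, `satellite`, `strand`,
#'   `start`, `identity`, `mismatches`, `aligned_span`; attributes
#'   `n_reads`, `n_unmapped`, `n_ambiguous`.
#' @export
map_reads_to_consensus <- function(reads, consensuses, min_identity = 0.8) {
  if (!is.data.frame(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)),
                    seq = as.character(reads))
  }
  if (inherits(consensuses, "satellite_consensus")) {
    consensuses <- list(consensuses)
  }
  names(consensuses) <- vapply(consensuses, `[[`, character(1), "name")
  n_reads <- nrow(reads)
  if (n_reads == 0L) {
    out <- tibble(read_id = character(), satellite = character(),
                  strand = character(), start = integer(),
                  identity = numeric(), mismatches = integer(),
                  aligned_span = integer())
    return(structure(out, n_reads = 0L, n_unmapped = 0L, n_ambiguous = 0L))
  }
  max_L <- max(vapply(consensuses, `[[`, numeric(1), "L"))
  seqs <- substr(reads$seq, 1L, 2L * max_L)
  lens <- nchar(seqs)

  best <- vector("list", length(consensuses))
  for (ci in seq_along(consensuses)) {
    cons <- consensuses[[ci]]
    L <- cons$L
    res <- tibble(read = integer(), strand = character(), start = integer(),
                  mismatches = integer(), span = integer())
    for (r in sort(unique(lens))) {
      idx <- which(lens == r)
      if (cons$circular) {
        n_pos <- L
        tiles <- ceiling((r + L - 1L) / L)
        tile <- strrep(cons$sequence, tiles)
      } else {
        if (r > L) next
        n_pos <- L - r + 1L
        tile <- cons$sequence
      }
      sf <- scan_tile(seqs[idx], tile, n_pos)
      sr <- scan_tile(revcomp(seqs[idx]), tile, n_pos)
      use_fwd <- sf$mismatches <= sr$mismatches
      res <- bind_rows(res, tibble(
        read = idx,
        strand = ifelse(use_fwd, "+", "-"),
        start = ifelse(use_fwd, sf$start, sr$start),
        mismatches = pmin(sf$mismatches, sr$mismatches),
        span = r
      ))
    }
    res$identity <- 1 - res$mismatches / res$span
    best[[ci]] <- res
  }

  # resolve across satellites per read
  id_mat <- matrix(-Inf, nrow = n_reads, ncol = length(consensuses))
  for (ci in seq_along(consensuses)) {
    id_mat[best[[ci]]$read, ci] <- best[[ci]]$identity
  }
  top <- apply(id_mat, 1L, max)
  n_top <- rowSums(abs(id_mat - top) < 1e-12)
  ambiguous <- n_top > 1L & top >= min_identity
  mapped <- top >= min_identity & !ambiguous
  which_sat <- max.col(id_mat, ties.method = "first")

  rows <- lapply(seq_along(consensuses), function(ci) {
    b <- best[[ci]]
    b <- b[mapped[b$read] & which_sat[b$read] == ci, , drop = FALSE]
    if (!nrow(b)) return(NULL)
    tibble(
      read_id = reads$read_id[b$read],
      satellite = names(consensuses)[ci],
      strand = b$strand, start = b$start, identity = b$identity,
      mismatches = b$mismatches, aligned_span = b$span
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(read_id = character(), satellite = character(),
                  strand = character(), start = integer(),
                  identity = numeric(), mismatches = integer(),
                  aligned_span = integer())
  }
  structure(out,
    n_reads = n_reads,
    n_unmapped = sum(!mapped & !ambiguous),
    n_ambiguous = sum(ambiguous)
  )
}

#' Fraction of reads mapping to each satellite consensus
#'
#' @inheritParams map_reads_to_consensus
#' @return Tibble with `satellite`, `n_mapped`, `n_reads`, `fraction`.
#' @export
mapped_fraction <- function(reads, consensuses, min_identity = 0.8) {
  if (inherits(consensuses, "satellite_consensus")) {
    consensuses <- list(consensuses)
  }
  aln <- map_reads_to_consensus(reads, consensuses, min_identity)
  n <- attr(aln, "n_reads")
  if (n == 0L) abort("no reads supplied; mapped fraction undefined")
  counts <- table(factor(aln$satellite,
                         levels = vapply(consensuses, `[[`, character(1),
                                         "name")))
  tibble(
    satellite = names(counts),
    n_mapped = as.integer(counts),
    n_reads = n,
    fraction = as.integer(counts) / n
  )
}

#' Pairwise difference between two reads anchored at the same site
#'
#' Counts mismatches over the overlapping aligned span of two reads that
#' map to the same satellite, strand and start position, then rescales to
#' the repeat-unit length: `d = mismatches * L / overlap`, so the value
#' reads as differences per full repeat unit regardless of read length.
#' `rescale = FALSE` returns raw mismatch counts. Pairs overlapping fewer
#' than `min_overlap` bases return `NA` (skipped).
#'
#' @param a,b Lists (or one-row data frames) with fields `seq`,
#'   `satellite`, `strand`, `start`; `seq` must already be oriented to
#'   the consensus strand.
#' @param unit_length Repeat unit length L.
#' @param rescale Rescale mismatches to per-unit differences?
#' @param min_overlap Minimum overlap in bp (default 30).
#' @return A single difference value `d_ij` (or `NA` if skipped).
#' @export
pairwise_difference <- function(a, b, unit_length, rescale = TRUE,
                                min_overlap = 30) {
  for (f in c("satellite", "strand", "start")) {
    if (!identical(a[[f]], b[[f]])) {
      abort(sprintf("reads are not anchored at the same site: `%s` differs", f))
    }
  }
  o <- min(nchar(a$seq), nchar(b$seq))
  if (o < min_overlap) return(NA_real_)
  m <- hamming(substr(a$seq, 1L, o), substr(b$seq, 1L, o))
  if (rescale) m * unit_length / o else as.numeric(m)
}

#' Convert a CDI value to percent nucleotide divergence
#'
#' A CDI of d differences per repeat unit of length L corresponds to
#' `100 * d / L` percent nucleotide divergence between two random repeat
#' copies: 17 differences on a 120-bp unit is ~14%; 30 is 25%.
#'
#' @param cdi CDI value(s), differences per repeat unit.
#' @param unit_length Repeat unit length L.
#' @return Percent divergence.
#' @examples
#' cdi_divergence(17, 120)
#' @export
cdi_divergence <- function(cdi, unit_length) {
  if (unit_length <= 0) abort("`unit_length` must be positive")
  100 * cdi / unit_length
}

# sample up to `cap` unordered pairs from m items (all pairs when they fit)
sample_pairs <- function(m, cap) {
  total <- m * (m - 1) / 2
  if (total <= cap) {
    i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    j <- unlist(lapply(seq_len(m - 1L), function(a) (a + 1L):m))
    return(cbind(i, j))
  }
  got <- matrix(integer(0), ncol = 2)
  while (nrow(got) < cap) {
    a <- sample.int(m, 2L * cap, replace = TRUE)
    b <- sample.int(m, 2L * cap, replace = TRUE)
    keep <- a != b
    p <- cbind(pmin(a, b), pmax(a, b))[keep, , drop = FALSE]
    got <- unique(rbind(got, p))
  }
  got[seq_len(cap), , drop = FALSE]
}

#' Centromere diversity index (CDI)
#'
#' Average number of sequence differences between independent satellite
#' repeats in one genome. Reads are partitioned by satellite, strand
#' (preventing comparison of a sequence with its own reverse complement)
#' and mapped start position; within every cell each read pair
#' contributes its mismatch count over the overlapping span, rescaled to
#' the repeat-unit length L, and the CDI is the average over all N
#' eligible pairs across both strands and all L positions. On a 120-bp
#' unit a CDI of 17 means two random repeat copies differ at ~17 sites
#' (~14% nucleotide divergence).
#'
#' Positions with many reads are subsampled to at most
#' `pairs_per_position_cap` pairs (seeded) per cell; below the cap the
#' exact all-pairs set is used.
#'
#' @param alignments Output of [map_reads_to_consensus()].
#' @param reads The reads that were mapped (tibble with `read_id`,
#'   `seq`).
#' @param consensuses The satellite consensus (or list) that was mapped
#'   against; supplies L per satellite.
#' @param pairs_per_position_cap Maximum pairs per (strand, position)
#'   cell (default 200).
#' @param min_overlap Minimum pair overlap in bp (default 30).
#' @param rescale Rescale differences to per-unit length (default TRUE)?
#' @param seed Seed for pair subsampling.
#' @return Tibble with one row per satellite: `satellite`, `cdi`,
#'   `n_pairs`, `n_positions`, plus the per-strand breakdown `cdi_fwd`,
#'   `n_pairs_fwd`, `cdi_rev`, `n_pairs_rev`. Satellites with no eligible
#'   pair get `NA` with a warning.
#' @export
centromere_diversity_index <- function(alignments, reads, consensuses,
                                       pairs_per_position_cap = 200,
                                       min_overlap = 30, rescale = TRUE,
                                       seed = NULL) {
  if (inherits(consensuses, "satellite_consensus")) {
    consensuses <- list(consensuses)
  }
  names(consensuses) <- vapply(consensuses, `[[`, character(1), "name")
  aln <- left_join(alignments, reads[, c("read_id", "seq")], by = "read_id")
  aln$seq <- substr(aln$seq, 1L, aln$aligned_span)
  flip <- aln$strand == "-"
  aln$seq[flip] <- revcomp(aln$seq[flip])

  with_seed(seed, {
    rows <- lapply(names(consensuses), function(sat) {
      L <- consensuses[[sat]]$L
      sub <- aln[aln$satellite == sat, , drop = FALSE]
      sums <- c(`+` = 0, `-` = 0)
      ns <- c(`+` = 0L, `-` = 0L)
      n_positions <- 0L
      if (nrow(sub)) {
        cells <- split(seq_len(nrow(sub)),
                       list(sub$strand, sub$start), drop = TRUE)
        for (cell in cells) {
          m <- length(cell)
          if (m < 2L) next
          strand <- sub$strand[cell[1L]]
          seqs <- sub$seq[cell]
          lens <- nchar(seqs)
          pr <- sample_pairs(m, pairs_per_position_cap)
          o <- pmin(lens[pr[, 1L]], lens[pr[, 2L]])
          ok <- o >= min_overlap
          if (!any(ok)) next
          pr <- pr[ok, , drop = FALSE]
          o <- o[ok]
          mat <- seq_char_matrix(stringr::str_pad(seqs, max(lens), "right",
                                                  pad = " "))
          mat[mat == " "] <- NA_character_
          mism <- colSums(
            mat[, pr[, 1L], drop = FALSE] != mat[, pr[, 2L], drop = FALSE],
            na.rm = TRUE
          )
          d <- if (rescale) mism * L / o else as.numeric(mism)
          sums[strand] <- sums[strand] + sum(d)
          ns[strand] <- ns[strand] + length(d)
          n_positions <- n_positions + 1L
        }
      }
      n_total <- sum(ns)
      if (n_total == 0L) {
        warn(sprintf(
          "no eligible read pairs for satellite '%s'; CDI undefined", sat
        ))
      }
      tibble(
        satellite = sat,
        cdi = if (n_total) sum(sums) / n_total else NA_real_,
        n_pairs = n_total, n_positions = n_positions,
        cdi_fwd = if (ns[["+"]]) sums[["+"]] / ns[["+"]] else NA_real_,
        n_pairs_fwd = ns[["+"]],
        cdi_rev = if (ns[["-"]]) sums[["-"]] / ns[["-"]] else NA_real_,
        n_pairs_rev = ns[["-"]]
      )
    })
    structure(bind_rows(rows),
              class = c("cdi_result", class(tibble())))
  })
}
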