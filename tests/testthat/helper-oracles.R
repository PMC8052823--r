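# Shared fixtures (built once per test run) and independent brute-force
# oracles that deliberately avoid the package's own code paths.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The study-condition scenario bundle (inbred-like / wild-like / phylo).
fixture_scenarios <- function() {
  cached("scenarios", function() scenario_fixtures(seed = 1))
}

# A small shared consensus for cheap unit tests.
fixture_consensus <- function() {
  cached("consensus", function() {
    satellite_consensus("minor_like", random_dna(120, seed = 42))
  })
}

# --- oracles -----------------------------------------------------------

# Reverse complement via Biostrings (independent of censat's stringi path).
oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Brute-force k-mer dictionary: base substring windows, Biostrings
# reverse complement, base table() tally — independent of the package's
# compiled counting path.
oracle_count_kmers <- function(seqs, k, canonical = TRUE) {
  windows <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }))
  windows <- windows[!grepl("[^ACGT]", windows)]
  if (canonical && length(windows)) {
    rc <- oracle_revcomp(windows)
    windows <- ifelse(rc < windows, rc, windows)
  }
  tab <- table(windows)
  data.frame(kmer = names(tab), count = as.numeric(tab))
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# All-pairs CDI over alignments (no cap, plain loops).
oracle_cdi <- function(aln, reads, L, min_overlap = 30, rescale = TRUE) {
  seqs <- reads$seq[match(aln$read_id, reads$read_id)]
  seqs <- substr(seqs, 1, aln$aligned_span)
  flip <- aln$strand == "-"
  seqs[flip] <- oracle_revcomp(seqs[flip])
  total <- 0
  n <- 0L
  key <- paste(aln$strand, aln$start)
  for (kk in unique(key)) {
    idx <- which(key == kk)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        i <- idx[a]; j <- idx[b]
        o <- min(nchar(seqs[i]), nchar(seqs[j]))
        if (o < min_overlap) next
        m <- oracle_hamming(substr(seqs[i], 1, o), substr(seqs[j], 1, o))
        total <- total + if (rescale) m * L / o else m
        n <- n + 1L
      }
    }
  }
  list(cdi = total / n, n_pairs = n)
}

# Brute-force polymorphism tally looping over (kmer, window, orientation).
oracle_poly_matrix <- function(kmers, freqs, consensus, k, h_max) {
  L <- nchar(consensus)
  circ <- paste0(consensus, substr(consensus, 1, k - 1))
  windows <- substring(circ, 1:L, 1:L + k - 1)
  probs <- matrix(0, nrow = 4, ncol = L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (qi in seq_along(kmers)) {
    q <- kmers[qi]
    hits <- data.frame(pos = integer(), orient = character(),
                       d = integer())
    for (p in 1:L) {
      df <- oracle_hamming(q, windows[p])
      dr <- oracle_hamming(q, oracle_revcomp(windows[p]))
      hits <- rbind(hits,
                    data.frame(pos = p, orient = "+", d = df),
                    data.frame(pos = p, orient = "-", d = dr))
    }
    best <- min(hits$d)
    if (best > h_max) next
    tied <- hits[hits$d == best, , drop = FALSE]
    w <- freqs[qi] / nrow(tied)
    for (r in seq_len(nrow(tied))) {
      oriented <- if (tied$orient[r] == "+") q else oracle_revcomp(q)
      chars <- strsplit(oriented, "")[[1]]
      for (t in 0:(k - 1)) {
        pos <- (tied$pos[r] - 1 + t) %% L + 1
        probs[chars[t + 1], pos] <- probs[chars[t + 1], pos] + w
      }
    }
  }
  sweep(probs, 2, colSums(probs), "/")
}

# Direct ML profile for heritability by dense solves (no eigen trick).
oracle_herit_loglik <- function(y, G, h) {
  n <- length(y)
  Gs <- G / mean(diag(G))
  V1 <- h * Gs + (1 - h) * diag(n)
  Vi <- solve(V1)
  one <- rep(1, n)
  mu <- as.numeric(one %*% Vi %*% y / (one %*% Vi %*% one))
  r <- y - mu
  s2 <- as.numeric(r %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi) + n * log(s2) +
            as.numeric(determinant(V1)$modulus) + n)
}
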