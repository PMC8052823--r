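#' Random DNA sequence
#'
#' Uniform ACGT background with a target GC fraction.
#'
#' @param n Length in bp.
#' @param gc Target GC fraction (default 0.5).
#' @param seed Integer seed.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.5, seed = NULL) {
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

#' Simulate a tandem satellite array with known heterogeneity
#'
#' Concatenates `copies` copies of a consensus repeat unit, mutating each
#' copy independently: every position of every copy is substituted with
#' probability `rate` (a scalar or a length-L per-position vector) to a
#' uniformly chosen different base. Optionally, shared variant sites are
#' planted first: at a given position, a fixed alternative base is
#' carried by a `frequency` fraction of copies (Bernoulli per copy),
#' emulating population-frequency polymorphisms such as those around the
#' CENP-B box. Every introduced substitution is recorded in a truth
#' table.
#'
#' Under the independent per-copy model, two random copies differ at a
#' site with probability `2p(1-p)` (to first order), so the expected
#' diversity index of the array is about `2 L p (1 - p)` differences per
#' unit.
#'
#' @param consensus A [satellite_consensus()] or ACGT string.
#' @param copies Number of repeat copies.
#' @param rate Per-position, per-copy substitution probability (scalar or
#'   length-L vector), in `[0, 1)`.
#' @param shared_variants Optional tibble/data frame with columns
#'   `position`, `alt`, `frequency`.
#' @param seed Integer seed; the result is deterministic given it.
#' @return List with `sequence` (the array), `truth` (tibble: `copy`,
#'   `position`, `ref`, `alt`, `source` = "iid" or "shared"),
#'   `consensus`, `copies`.
#' @export
simulate_array <- function(consensus, copies, rate = 0,
                           shared_variants = NULL, seed = NULL) {
  if (is.character(consensus)) {
    consensus <- satellite_consensus("satellite", consensus)
  }
  L <- consensus$L
  rate <- rep(rate, length.out = L)
  if (any(rate < 0 | rate >= 1)) abort("`rate` must be in [0, 1)")
  bases <- c("A", "C", "G", "T")
  cons_chars <- strsplit(consensus$sequence, "")[[1L]]
  with_seed(seed, {
    mat <- matrix(cons_chars, nrow = L, ncol = copies)
    truth <- list()
    if (!is.null(shared_variants) && nrow(shared_variants)) {
      for (r in seq_len(nrow(shared_variants))) {
        pos <- shared_variants$position[r]
        alt <- shared_variants$alt[r]
        f <- shared_variants$frequency[r]
        if (f <= 0 || f >= 1) abort("shared variant frequencies must be in (0, 1)")
        carriers <- which(runif(copies) < f)
        if (length(carriers)) {
          mat[pos, carriers] <- alt
          truth[[length(truth) + 1L]] <- tibble(
            copy = carriers, position = pos, ref = cons_chars[pos],
            alt = alt, source = "shared"
          )
        }
      }
    }
    hit <- which(matrix(runif(L * copies), nrow = L) < rate)
    if (length(hit)) {
      pos <- (hit - 1L) %% L + 1L
      cp <- (hit - 1L) %/% L + 1L
      old <- mat[hit]
      # uniform over the three other bases
      alt <- vapply(old, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      mat[hit] <- alt
      truth[[length(truth) + 1L]] <- tibble(
        copy = cp, position = pos, ref = old, alt = alt, source = "iid"
      )
    }
    list(
      sequence = paste(mat, collapse = ""),
      truth = if (length(truth)) arrange(bind_rows(truth), .data$copy,
                                         .data$position)
              else tibble(copy = integer(), position = integer(),
                          ref = character(), alt = character(),
                          source = character()),
      consensus = consensus,
      copies = copies
    )
  })
}

#' Simulate a genome with embedded satellite arrays
#'
#' Generates a random background sequence and inserts simulated arrays
#' at recorded coordinates. With `positions = NULL` the arrays are
#' inserted at evenly spaced background offsets; user-supplied positions
#' (1-based background offsets, one per array) must be strictly
#' increasing and within the background, otherwise placements are
#' rejected as overlapping/invalid.
#'
#' @param background_length Background length in bp (excluding arrays).
#' @param arrays List of arrays from [simulate_array()] (may be empty).
#' @param gc Background GC fraction target.
#' @param positions Optional insertion offsets into the background.
#' @param seed Integer seed.
#' @return List with `sequence`, `truth` (tibble: `name`, `start`, `end`,
#'   `copies`, `unit_length` in final-genome coordinates), `arrays`.
#' @export
simulate_genome <- function(background_length, arrays = list(), gc = 0.5,
                            positions = NULL, seed = NULL) {
  bg <- random_dna(background_length, gc = gc,
                   seed = child_seed(seed, "background") %||% NULL)
  n_arr <- length(arrays)
  if (n_arr == 0L) {
    return(list(sequence = bg,
                truth = tibble(name = character(), start = integer(),
                               end = integer(), copies = integer(),
                               unit_length = integer()),
                arrays = arrays))
  }
  if (is.null(positions)) {
    positions <- round(seq(1, background_length + 1,
                           length.out = n_arr + 2L))[2:(n_arr + 1L)]
  }
  if (length(positions) != n_arr ||
      any(diff(positions) <= 0) ||
      any(positions < 1 | positions > background_length + 1)) {
    abort("overlapping or invalid array placements")
  }
  pieces <- character(0)
  truth <- list()
  prev <- 1L
  offset <- 0L
  for (i in seq_len(n_arr)) {
    pieces <- c(pieces, substr(bg, prev, positions[i] - 1L))
    arr_len <- nchar(arrays[[i]]$sequence)
    start <- positions[i] + offset
    truth[[i]] <- tibble(
      name = arrays[[i]]$consensus$name,
      start = start, end = start + arr_len - 1L,
      copies = arrays[[i]]$copies,
      unit_length = arrays[[i]]$consensus$L
    )
    pieces <- c(pieces, arrays[[i]]$sequence)
    offset <- offset + arr_len
    prev <- positions[i]
  }
  pieces <- c(pieces, substr(bg, prev, background_length))
  list(sequence = paste(pieces, collapse = ""),
       truth = bind_rows(truth), arrays = arrays)
}

#' Simulate shotgun reads with optional GC-dependent thinning
#'
#' Draws uniform fragment starts on both strands of the genome at the
#' requested candidate depth, then keeps each candidate read with
#' probability `gc_bias(read GC fraction)` — an acceptance-probability
#' (thinning) model of library GC bias, chosen so expected counts stay
#' analytic. Per-base sequencing errors are i.i.d. substitutions to a
#' uniformly chosen different base. The realised mean depth is
#' `depth * mean acceptance`.
#'
#' @param genome A DNA string or the list from [simulate_genome()].
#' @param depth Candidate sequencing depth (fold coverage before
#'   thinning).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param gc_bias `NULL` (no bias) or a function mapping GC fraction in
#'   `[0, 1]` to an acceptance probability in `(0, 1]`.
#' @param seed Integer seed.
#' @return Tibble of kept reads: `read_id`, `seq`, `qual`, plus truth
#'   columns `true_start` and `true_strand`; attributes `n_candidates`,
#'   `mean_acceptance`, `genome_length`.
#' @export
simulate_reads <- function(genome, depth = 20, read_length = 100,
                           error_rate = 0, gc_bias = NULL, seed = NULL) {
  seq <- if (is.list(genome)) genome$sequence else genome
  G <- nchar(seq)
  if (read_length > G) abort("`read_length` exceeds genome length")
  if (depth <= 0) abort("`depth` must be positive")
  n_cand <- max(1L, round(depth * G / read_length))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    starts <- sample.int(G - read_length + 1L, n_cand, replace = TRUE)
    strands <- sample(c("+", "-"), n_cand, replace = TRUE)
    reads <- substring(seq, starts, starts + read_length - 1L)
    reads[strands == "-"] <- revcomp(reads[strands == "-"])
    if (!is.null(gc_bias)) {
      p <- gc_bias(gc_fraction(reads))
      if (any(p <= 0 | p > 1)) {
        abort("`gc_bias` must return acceptance probabilities in (0, 1]")
      }
      keep <- runif(n_cand) < p
      mean_acc <- mean(p)
    } else {
      keep <- rep(TRUE, n_cand)
      mean_acc <- 1
    }
    reads <- reads[keep]
    starts <- starts[keep]
    strands <- strands[keep]
    if (error_rate > 0 && length(reads)) {
      mat <- seq_char_matrix(reads)
      hit <- which(matrix(runif(length(mat)), nrow = nrow(mat)) < error_rate)
      if (length(hit)) {
        mat[hit] <- vapply(mat[hit],
                           function(b) sample(setdiff(bases, b), 1L),
                           character(1))
      }
      reads <- apply(mat, 2L, paste, collapse = "")
    }
    structure(
      tibble(
        read_id = sprintf("read%06d", seq_along(reads)),
        seq = reads,
        qual = strrep("I", read_length),
        true_start = starts,
        true_strand = strands
      ),
      n_candidates = n_cand, mean_acceptance = mean_acc, genome_length = G
    )
  })
}

#' Named scenario bundles with known ground truth
#'
#' Builds the package's reference test scenarios, deterministic given
#' `seed`:
#'
#' * `inbred_like`: a large, homogeneous satellite array (2,000 copies,
#'   per-position heterogeneity rate 0.02) — the inbred-strain regime of
#'   high copy number and low repeat diversity.
#' * `wild_like`: a small, heterogeneous array (300 copies, rate 0.10) —
#'   the wild-caught regime of reduced copy number and elevated
#'   heterogeneity. The planted copy ratio between the two scenarios is
#'   2000/300 (about 6.7x).
#' * `phylo`: a 32-tip tree with a pure Brownian-motion trait and an
#'   i.i.d. noise trait for heritability checks.
#'
#' Both genome scenarios share one synthetic 120-bp consensus and a
#' random background, and carry reads simulated at the stated depth.
#'
#' @param seed Integer seed (default 1).
#' @param depth Candidate read depth for both genome scenarios.
#' @param read_length Read length in bp.
#' @param background_length Background length in bp.
#' @return Named list with elements `consensus`, `inbred_like`,
#'   `wild_like` (each: `array`, `genome`, `reads`, `copies`, `rate`) and
#'   `phylo` (`tree`, `G`, `trait_bm`, `trait_noise`).
#' @export
scenario_fixtures <- function(seed = 1, depth = 20, read_length = 100,
                              background_length = 50000) {
  consensus <- satellite_consensus(
    "minor_like", random_dna(120, seed = child_seed(seed, "consensus"))
  )
  build <- function(label, copies, rate) {
    arr <- simulate_array(consensus, copies = copies, rate = rate,
                          seed = child_seed(seed, paste0(label, "_array")))
    gen <- simulate_genome(background_length, list(arr),
                           seed = child_seed(seed, paste0(label, "_genome")))
    rds <- simulate_reads(gen, depth = depth, read_length = read_length,
                          seed = child_seed(seed, paste0(label, "_reads")))
    list(array = arr, genome = gen, reads = rds, copies = copies,
         rate = rate)
  }
  tree <- with_seed(child_seed(seed, "tree"), ape::rcoal(32))
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  G <- phylo_covariance(tree)
  trait_bm <- with_seed(child_seed(seed, "trait_bm"), {
    z <- rnorm(nrow(G))
    ch <- chol(G + diag(1e-10, nrow(G)))
    setNames(as.numeric(crossprod(ch, z)), rownames(G))
  })
  trait_noise <- with_seed(child_seed(seed, "trait_noise"),
                           setNames(rnorm(nrow(G)), rownames(G)))
  list(
    consensus = consensus,
    inbred_like = build("inbred", copies = 2000, rate = 0.02),
    wild_like = build("wild", copies = 300, rate = 0.10),
    phylo = list(tree = tree, G = G, trait_bm = trait_bm,
                 trait_noise = trait_noise)
  )
}
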