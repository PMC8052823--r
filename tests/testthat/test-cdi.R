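test_that("exact consensus substrings map with full identity on both strands", {
  cons <- fixture_consensus()
  read <- substr(cons$sequence, 10, 109)
  aln <- map_reads_to_consensus(tibble::tibble(read_id = "r1", seq = read),
                                cons)
  expect_equal(aln$satellite, "minor_like")
  expect_equal(aln$strand, "+")
  expect_equal(aln$start, 10L)
  expect_equal(aln$identity, 1)

  aln_rc <- map_reads_to_consensus(
    tibble::tibble(read_id = "r1rc", seq = oracle_revcomp(read)), cons
  )
  expect_equal(aln_rc$strand, "-")
  expect_equal(aln_rc$start, 10L)
  expect_equal(aln_rc$identity, 1)

  # a read spanning the unit junction still maps (circular consensus)
  arr <- simulate_array(cons, copies = 2, rate = 0, seed = 1)
  junction <- substr(arr$sequence, 80, 179)
  aln_j <- map_reads_to_consensus(
    tibble::tibble(read_id = "j", seq = junction), cons
  )
  expect_equal(aln_j$start, 80L)
  expect_equal(aln_j$identity, 1)
})

test_that("random reads do not reach the identity threshold", {
  set.seed(210)
  cons <- fixture_consensus()
  reads <- tibble::tibble(
    read_id = paste0("r", 1:100),
    seq = vapply(1:100, function(i) random_dna(100), character(1))
  )
  aln <- map_reads_to_consensus(reads, cons, min_identity = 0.8)
  expect_equal(nrow(aln), 0L)
  expect_equal(attr(aln, "n_unmapped"), 100L)
})

test_that("mapped fraction approximates the array share of sampled reads", {
  cons <- fixture_consensus()
  arr <- simulate_array(cons, copies = 100, rate = 0, seed = 220)
  gen <- simulate_genome(12000, list(arr), seed = 221)  # array share = 0.5
  rds <- simulate_reads(gen, depth = 10, read_length = 100, seed = 222)
  mf <- mapped_fraction(rds, cons)
  expect_equal(mf$fraction, 0.5, tolerance = 0.1)

  none <- simulate_reads(random_dna(10000, seed = 223), depth = 5,
                         read_length = 100, seed = 224)
  mf0 <- mapped_fraction(none, cons)
  expect_equal(mf0$fraction, 0)
  expect_error(mapped_fraction(tibble::tibble(read_id = character(),
                                              seq = character()), cons),
               "no reads")
})

test_that("pairwise differences rescale mismatches to the repeat unit", {
  base <- list(seq = strrep("A", 120), satellite = "s", strand = "+",
               start = 1L)
  same <- base
  expect_equal(pairwise_difference(base, same, unit_length = 120), 0)

  three <- base
  substr(three$seq, 5, 5) <- "C"
  substr(three$seq, 20, 20) <- "G"
  substr(three$seq, 50, 50) <- "T"
  expect_equal(pairwise_difference(base, three, unit_length = 120), 3)

  # 60-bp overlap with 3 mismatches -> 3 * 120 / 60 = 6
  short <- list(seq = substr(three$seq, 1, 60), satellite = "s",
                strand = "+", start = 1L)
  long <- base
  expect_equal(pairwise_difference(long, short, unit_length = 120), 6)
  expect_equal(pairwise_difference(long, short, unit_length = 120,
                                   rescale = FALSE), 3)

  tiny <- list(seq = substr(base$seq, 1, 10), satellite = "s",
               strand = "+", start = 1L)
  expect_true(is.na(pairwise_difference(base, tiny, unit_length = 120)))

  other <- base
  other$start <- 2L
  expect_error(pairwise_difference(base, other, unit_length = 120),
               "same site")
})

test_that("a homogeneous array has CDI zero", {
  cons <- fixture_consensus()
  arr <- simulate_array(cons, copies = 200, rate = 0, seed = 230)
  rds <- simulate_reads(arr$sequence, depth = 8, read_length = 100,
                        seed = 232)
  aln <- map_reads_to_consensus(rds, cons)
  cdi <- centromere_diversity_index(aln, rds, cons, seed = 233)
  expect_equal(cdi$cdi, 0)
  expect_gt(cdi$n_pairs, 0)
})

test_that("CDI equals the brute-force all-pairs oracle on small read sets", {
  cons <- fixture_consensus()
  arr <- simulate_array(cons, copies = 50, rate = 0.05, seed = 240)
  rds <- simulate_reads(arr$sequence, depth = 0.8, read_length = 100,
                        seed = 241)
  expect_lte(nrow(rds), 50)
  aln <- map_reads_to_consensus(rds, cons)
  cdi <- centromere_diversity_index(aln, rds, cons,
                                    pairs_per_position_cap = 1e6,
                                    seed = 242)
  oracle <- oracle_cdi(aln, rds, L = 120)
  expect_equal(cdi$n_pairs, oracle$n_pairs)
  expect_equal(cdi$cdi, oracle$cdi, tolerance = 1e-12)
})

test_that("CDI matches the analytic expectation under i.i.d. heterogeneity", {
  cons <- fixture_consensus()
  p <- 0.05
  arr <- simulate_array(cons, copies = 400, rate = p, seed = 250)
  gen <- simulate_genome(20000, list(arr), seed = 251)
  rds <- simulate_reads(gen, depth = 15, read_length = 100, seed = 252)
  aln <- map_reads_to_consensus(rds, cons)
  cdi <- centromere_diversity_index(aln, rds, cons, seed = 253)
  expected <- 2 * 120 * p * (1 - p)
  expect_lt(abs(cdi$cdi - expected) / expected, 0.15)
  expect_lte(cdi$cdi, 120)
  expect_gte(cdi$cdi, 0)
})

test_that("CDI is invariant to globally reverse-complementing all reads", {
  cons <- fixture_consensus()
  arr <- simulate_array(cons, copies = 100, rate = 0.08, seed = 260)
  gen <- simulate_genome(8000, list(arr), seed = 261)
  rds <- simulate_reads(gen, depth = 6, read_length = 100, seed = 262)
  aln <- map_reads_to_consensus(rds, cons)
  cdi <- centromere_diversity_index(aln, rds, cons,
                                    pairs_per_position_cap = 1e6)

  flipped <- rds
  flipped$seq <- oracle_revcomp(flipped$seq)
  aln_f <- map_reads_to_consensus(flipped, cons)
  cdi_f <- centromere_diversity_index(aln_f, flipped, cons,
                                      pairs_per_position_cap = 1e6)
  expect_equal(cdi_f$cdi, cdi$cdi, tolerance = 1e-12)
  # strand labels swap but the partition is preserved
  expect_equal(cdi_f$n_pairs, cdi$n_pairs)
})

test_that("sequencing error inflates CDI by about 2 L e", {
  cons <- fixture_consensus()
  e <- 0.01
  arr <- simulate_array(cons, copies = 300, rate = 0.05, seed = 270)
  gen <- simulate_genome(15000, list(arr), seed = 271)
  cdi_at <- function(err, seed) {
    rds <- simulate_reads(gen, depth = 12, read_length = 100,
                          error_rate = err, seed = seed)
    aln <- map_reads_to_consensus(rds, cons)
    centromere_diversity_index(aln, rds, cons, seed = seed + 1)$cdi
  }
  clean <- cdi_at(0, 272)
  noisy <- cdi_at(e, 272)
  inflation <- noisy - clean
  expect_lt(abs(inflation - 2 * 120 * e) / (2 * 120 * e), 0.35)
})

test_that("the wild-like scenario shows higher CDI and fewer copies than inbred-like", {
  fx <- fixture_scenarios()
  get_cdi <- function(sc, seed) {
    aln <- map_reads_to_consensus(sc$reads, fx$consensus)
    centromere_diversity_index(aln, sc$reads, fx$consensus, seed = seed)$cdi
  }
  cdi_inbred <- get_cdi(fx$inbred_like, 280)
  cdi_wild <- get_cdi(fx$wild_like, 281)
  expect_gt(cdi_wild, cdi_inbred)
  expect_gt(fx$inbred_like$copies, fx$wild_like$copies)
})

test_that("undefined CDI warns with a diagnostic", {
  cons <- fixture_consensus()
  reads <- tibble::tibble(read_id = "solo",
                          seq = substr(cons$sequence, 1, 100))
  aln <- map_reads_to_consensus(reads, cons)
  expect_warning(
    cdi <- centromere_diversity_index(aln, reads, cons),
    "no eligible"
  )
  expect_true(is.na(cdi$cdi))
})
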