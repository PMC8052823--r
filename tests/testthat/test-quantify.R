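test_that("copy number is 10^median with exact array-length arithmetic", {
  est <- estimate_copy_number(rep(5, 11), unit_length = 234)
  expect_equal(est$copies, 1e5)

  # 1,320 minor satellite copies over 40 chromosomes -> 3.96 kb each
  est <- estimate_copy_number(log10(1320), unit_length = 120)
  expect_equal(est$per_chromosome_bp, 3960)

  est <- estimate_copy_number(rep(2.3, 7), unit_length = 120)
  expect_equal(est$copies, 10^2.3, tolerance = 1e-12)

  # even count: median is the mean of the middle two
  est <- estimate_copy_number(c(1, 2, 3, 4), unit_length = 120)
  expect_equal(est$median_normalized, 2.5)

  # arithmetic identity
  expect_equal(est$per_chromosome_bp * 40 / 120, est$copies)
})

test_that("missingness is pruned and flags below-detection estimates", {
  est <- estimate_copy_number(c(2, NA, 2, 2), unit_length = 120)
  expect_equal(est$copies, 100)
  expect_equal(est$n_missing, 1L)
  expect_false(est$below_detection)

  est <- estimate_copy_number(c(2, NA, NA, NA), unit_length = 120)
  expect_true(est$below_detection)
  expect_true(is.na(est$copies))

  est <- estimate_copy_number(rep(NA_real_, 5), unit_length = 120)
  expect_true(est$below_detection)
})

test_that("fold range reproduces the printed contrasts", {
  expect_equal(round(fold_range(c(260220, 1320))), 197)
  expect_equal(round(fold_range(c(37240, 2900))), 13)
  expect_equal(fold_range(c(7, 7, 7)), 1)
  expect_error(fold_range(c(10, 0)), "> 0")
})

test_that("satellite frequency queries deduplicate and carry missing values", {
  cons <- fixture_consensus()
  cks <- consensus_kmer_set(cons, 31)
  tab <- count_kmers(random_dna(5000, seed = 130), k = 31)
  ref <- count_kmers(random_dna(5000, seed = 131), k = 31)
  panel <- select_unique_kmers(ref, n = 100, seed = 132)
  # consensus absent from the reads: every value missing
  model <- suppressWarnings(fit_gc_model(tab, panel))
  prof <- normalize_profile(tab, model, unique(cks$canonical))
  fr <- satellite_kmer_frequencies(prof, cks)
  expect_lte(nrow(fr), 120L)
  expect_true(all(is.na(fr$normalized)))
  est <- estimate_copy_number(fr, unit_length = 120)
  expect_true(est$below_detection)
})

test_that("a planted uniform array yields a tight frequency distribution", {
  cons <- fixture_consensus()
  arr <- simulate_array(cons, copies = 500, rate = 0, seed = 140)
  gen <- simulate_genome(50000, list(arr), seed = 141)
  rds <- simulate_reads(gen, depth = 20, read_length = 100, seed = 142)
  tab <- count_kmers(rds, 15)
  panel <- select_unique_kmers(count_reference_kmers(gen$sequence, 15),
                               n = 20000, seed = 143)
  model <- fit_gc_model(tab, panel)
  cks <- consensus_kmer_set(cons, 15)
  fr <- satellite_kmer_frequencies(
    normalize_profile(tab, model, unique(cks$canonical)), cks
  )
  expect_lt(IQR(fr$normalized, na.rm = TRUE), 0.1)
})

test_that("copy-number recovery is accurate and monotone on matched seeds", {
  cons <- fixture_consensus()
  est <- vapply(c(100, 1000), function(C) {
    arr <- simulate_array(cons, copies = C, rate = 0, seed = 150)
    gen <- simulate_genome(50000, list(arr), seed = 151)
    rds <- simulate_reads(gen, depth = 20, read_length = 100, seed = 152)
    tab <- count_kmers(rds, 15)
    panel <- select_unique_kmers(count_reference_kmers(gen$sequence, 15),
                                 n = 20000, seed = 153)
    model <- fit_gc_model(tab, panel)
    cks <- consensus_kmer_set(cons, 15)
    fr <- satellite_kmer_frequencies(
      normalize_profile(tab, model, unique(cks$canonical)), cks
    )
    estimate_copy_number(fr, unit_length = 120)$copies
  }, numeric(1))
  expect_lt(abs(est[1] - 100) / 100, 0.1)
  expect_lt(abs(est[2] - 1000) / 1000, 0.1)
  expect_gt(est[2], est[1])
})

test_that("variance scan matches hand values and a brute-force loop", {
  mk_tab <- function(seqs, bases) {
    tab <- count_kmers(seqs, k = 15)
    attr(tab, "total_read_bases") <- bases
    tab
  }
  s <- random_dna(60, seed = 160)
  t1 <- mk_tab(s, 1000)
  t2 <- mk_tab(s, 1000)
  scan <- kmer_variance_scan(list(t1, t2), top_n = 10, genome_size = 1000)
  expect_true(all(scan$variance == 0))

  # F values {0, 2}: variance ((0-1)^2 + (2-1)^2) / 1 = 2
  a <- mk_tab("AAAAAAAAAAAAAAA", 500)          # one k-mer, count 1, F = 1/0.5 = 2
  b <- mk_tab("CCCCCCCCCCCCCCC", 500)
  scan <- kmer_variance_scan(list(a, b), top_n = 10, genome_size = 1000)
  expect_equal(sort(unique(scan$variance)), 2)

  # brute-force equivalence on random tables
  set.seed(161)
  tabs <- lapply(1:3, function(i) mk_tab(random_dna(400, seed = 161 + i),
                                         2000))
  scan <- kmer_variance_scan(tabs, top_n = 50, genome_size = 2000)
  depth <- 1  # 2000 / 2000
  all_kmers <- sort(unique(unlist(lapply(tabs, `[[`, "kmer"))))
  ref_var <- vapply(all_kmers, function(km) {
    f <- vapply(tabs, function(t) {
      c0 <- t$count[match(km, t$kmer)]
      if (is.na(c0)) 0 else c0 / depth
    }, numeric(1))
    var(f)
  }, numeric(1))
  ref_top <- sort(ref_var, decreasing = TRUE)[1:50]
  expect_equal(scan$variance, unname(ref_top))
  expect_error(kmer_variance_scan(list(a)), "2 samples")
})

test_that("satellite k-mers dominate the variance scan under a copy contrast", {
  cons <- fixture_consensus()
  mk <- function(copies, seed) {
    arr <- simulate_array(cons, copies, rate = 0, seed = seed)
    gen <- simulate_genome(20000, list(arr), seed = seed + 1)
    rds <- simulate_reads(gen, depth = 10, read_length = 100,
                          seed = seed + 2)
    count_kmers(rds, 15)
  }
  scan <- kmer_variance_scan(list(mk(50, 170), mk(500, 180)),
                             top_n = 100, genome_size = 50000)
  cks <- consensus_kmer_set(cons, 15)
  expect_gt(mean(scan$kmer %in% cks$canonical), 0.9)
})

test_that("variance partition matches a hand-computed balanced ANOVA", {
  d <- data.frame(
    y = c(1, 2, 1, 3, 5, 6, 5, 7),
    A = rep(c("x", "y"), each = 4),
    B = rep(c("p", "q"), 4)
  )
  vp <- partition_variance(d, "y", c("A", "B"))
  # by hand: grand mean 3.75; A means 1.75/5.75 -> SS_A = 32; B means
  # 3/4.5 -> SS_B = 4.5; total SS = 37.5; residual = 1
  expect_equal(vp$sum_sq[vp$term == "A"], 32)
  expect_equal(vp$sum_sq[vp$term == "B"], 4.5)
  expect_equal(vp$sum_sq[vp$term == "Residuals"], 1)
  expect_equal(vp$percent_variance[vp$term == "A"], 100 * 32 / 37.5)
  expect_equal(sum(vp$percent_variance), 100, tolerance = 1e-6)

  # response fully determined by one factor
  d2 <- data.frame(y = rep(c(1, 5), each = 3), g = rep(c("a", "b"), each = 3))
  vp2 <- suppressWarnings(partition_variance(d2, "y", "g"))
  expect_equal(vp2$percent_variance[vp2$term == "g"], 100)

  # single-level factor contributes 0 with a warning
  d3 <- data.frame(y = rnorm(8), g = rep(c("a", "b"), 4), h = "only")
  expect_warning(vp3 <- partition_variance(d3, "y", c("g", "h")),
                 "single level")
  expect_equal(vp3$percent_variance[vp3$term == "h"], 0)
})

test_that("under a null response the factor share matches its df share", {
  set.seed(190)
  pct <- replicate(200, {
    d <- data.frame(y = rnorm(20), g = rep(letters[1:4], 5))
    vp <- partition_variance(d, "y", "g")
    vp$percent_variance[vp$term == "g"]
  })
  # E[% variance] = df_factor / df_total = 3 / 19
  expect_lt(abs(mean(pct) - 100 * 3 / 19), 2.5)
})
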