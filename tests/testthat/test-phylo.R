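test_that("phylogenetic covariance follows shared-path arithmetic", {
  G <- phylo_covariance("((A:1,B:1):1,C:2);")
  expect_equal(G["A", "B"], 1)
  expect_equal(unname(diag(G)[c("A", "B", "C")]), c(2, 2, 2))
  expect_equal(G["A", "C"], 0)

  # star tree with unit branches: identity matrix
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_covariance(star)), diag(4), ignore_attr = TRUE)

  # random trees give PSD matrices
  set.seed(400)
  for (i in 1:5) {
    G <- phylo_covariance(ape::rtree(20))
    expect_true(all(eigen(G, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-9))
    expect_equal(G, t(G))
  }

  # pruning and error contracts
  G3 <- phylo_covariance("((A:1,B:1):1,C:2);", tips = c("A", "B"))
  expect_equal(rownames(G3), c("A", "B"))
  no_bl <- ape::read.tree(text = "((A,B),C);")
  expect_error(phylo_covariance(no_bl), "branch lengths")
  dup <- ape::read.tree(text = "((A:1,A:1):1,C:2);")
  expect_error(phylo_covariance(dup), "duplicate")
  expect_error(phylo_covariance("((A:1,B:1):1,C:2);", tips = "Z"),
               "not in tree")
})

test_that("the profile likelihood matches a dense GLS oracle", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  y <- fx$phylo$trait_bm
  ws <- censat:::herit_workspace(y, G)
  for (h in c(0, 0.25, 0.5, 0.9)) {
    expect_equal(censat:::herit_profile(ws, h)$loglik,
                 oracle_herit_loglik(unname(y), G, h), tolerance = 1e-8)
  }
})

test_that("heritability recovers the simulated variance mixture", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  n <- nrow(G)
  ch <- chol(G + diag(1e-10, n))

  set.seed(410)
  h_bm <- replicate(40, {
    tr <- setNames(as.numeric(crossprod(ch, rnorm(n))), rownames(G))
    estimate_heritability(tr, G)$h2
  })
  expect_gte(median(h_bm), 0.9)

  h_noise <- replicate(40, {
    estimate_heritability(setNames(rnorm(n), rownames(G)), G)$h2
  })
  expect_lte(median(h_noise), 0.1)

  # 50/50 mixture at n = 64 (balanced tree, unit depth): the bounded ML
  # mixing ratio has wide sampling spread (sd ~ 0.22, identical to an
  # independent lambda-model fit) and a mild downward bias from the
  # boundary pile at 0, so the check is on the center of the estimate
  # distribution (~0.40 at truth 0.5) rather than per-replicate
  # closeness
  set.seed(411)
  tree64 <- ape::stree(64, "balanced")
  tree64$edge.length <- rep(1 / 6, nrow(tree64$edge))
  G64 <- phylo_covariance(tree64)
  ch64 <- chol(G64 + diag(1e-10, 64))
  h_mix <- replicate(60, {
    bm <- as.numeric(crossprod(ch64, rnorm(64)))
    tr <- setNames(sqrt(0.5) * bm + sqrt(0.5) * rnorm(64), rownames(G64))
    estimate_heritability(tr, G64)$h2
  })
  expect_gt(mean(h_mix), 0.3)
  expect_lt(mean(h_mix), 0.65)
  expect_gt(median(h_mix), 0.3)
  expect_lt(median(h_mix), 0.7)
  expect_lt(sd(h_mix), 0.35)
})

test_that("the bounded fit agrees with an independent lambda-model fit", {
  skip_if_not_installed("phytools")
  fx <- fixture_scenarios()
  tree <- fx$phylo$tree  # ultrametric, height 1: lambda model == our mixture
  G <- fx$phylo$G
  ch <- chol(G + diag(1e-10, nrow(G)))
  set.seed(420)
  agree <- replicate(10, {
    bm <- as.numeric(crossprod(ch, rnorm(32)))
    tr <- setNames(sqrt(0.6) * bm + sqrt(0.4) * rnorm(32), rownames(G))
    ours <- estimate_heritability(tr, G)
    ps <- phytools::phylosig(tree, tr, method = "lambda")
    c(ours = ours$h2, lambda = min(max(ps$lambda, 0), 1))
  })
  expect_lt(median(abs(agree["ours", ] - agree["lambda", ])), 0.05)
})

test_that("H2 is invariant to trait affine transforms and branch rescaling", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  y <- fx$phylo$trait_bm + 0.3 * fx$phylo$trait_noise
  base <- estimate_heritability(y, G)
  shifted <- estimate_heritability(100 + 7 * y, G)
  expect_equal(shifted$h2, base$h2, tolerance = 1e-5)
  scaled_G <- estimate_heritability(y, 13.7 * G)
  expect_equal(scaled_G$h2, base$h2, tolerance = 1e-5)
})

test_that("degenerate traits are rejected", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  expect_error(estimate_heritability(setNames(rep(1, 32), rownames(G)), G),
               "constant")
  expect_error(
    estimate_heritability(setNames(rnorm(3), rownames(G)[1:3]), G[1:3, 1:3]),
    "4 tips"
  )
  y <- fx$phylo$trait_bm
  expect_error(estimate_heritability(y[1:20], G), "missing for tips")
})

test_that("permutation p-values follow the +1-smoothed one-sided formula", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  y <- fx$phylo$trait_bm

  pv <- permutation_pvalue(y, G, n_perm = 200, seed = 430)
  perms <- attr(pv, "h2_perm")
  expect_length(perms, 200L)
  expect_equal(pv$p_value, (1 + sum(perms >= pv$h2_observed)) / 201)
  expect_gt(pv$p_value, 0)
  expect_lte(pv$p_value, 1)

  # determinism under a fixed seed
  pv2 <- permutation_pvalue(y, G, n_perm = 200, seed = 430)
  expect_equal(pv2$p_value, pv$p_value)
  expect_error(permutation_pvalue(y, G, n_perm = 0), "at least 1")

  # a strong phylogenetic signal is detected at the smallest attainable p
  expect_equal(pv$p_value, 1 / 201, tolerance = 1e-12)
})

test_that("null permutation p-values are valid (superuniform) and power is monotone", {
  fx <- fixture_scenarios()
  G <- fx$phylo$G
  n <- nrow(G)
  ch <- chol(G + diag(1e-10, n))
  set.seed(440)
  reps <- 60
  n_perm <- 99
  p_by_signal <- sapply(c(0, 0.5, 1), function(sig) {
    replicate(reps, {
      bm <- as.numeric(crossprod(ch, rnorm(n)))
      tr <- setNames(sqrt(sig) * bm + sqrt(1 - sig) * rnorm(n), rownames(G))
      permutation_pvalue(tr, G, n_perm = n_perm,
                         seed = sample.int(1e6, 1))$p_value
    })
  })
  # validity under the null: the empirical CDF never exceeds uniform by
  # more than Monte Carlo error (the H2 statistic's boundary atom makes
  # the p-value conservative, never anti-conservative)
  xs <- seq(0.01, 0.99, by = 0.01)
  excess <- max(ecdf(p_by_signal[, 1])(xs) - xs)
  expect_lt(excess, 2.5 * sqrt(0.25 / reps))
  # monotone power at alpha = 0.05
  rej <- colMeans(p_by_signal <= 0.05)
  expect_lte(rej[1], 0.1)
  expect_lt(rej[1], rej[2])
  expect_lte(rej[2], rej[3])
  expect_gt(rej[3], 0.8)
})

test_that("tidy and glance expose the fit in broom style", {
  fx <- fixture_scenarios()
  fit <- estimate_heritability(fx$phylo$trait_bm, fx$phylo$G,
                               metric_name = "copy_number")
  td <- tidy(fit)
  expect_equal(td$term, c("h2", "sigma2_phylo", "sigma2_resid", "mu"))
  gl <- glance(fit)
  expect_equal(gl$n, 32L)
  expect_equal(gl$h2, fit$h2)
})
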