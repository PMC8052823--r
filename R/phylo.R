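#' Phylogenetic variance-covariance matrix from a tree
#'
#' `G[i, j]` is the shared root-to-MRCA path length of tips i and j (the
#' expected trait covariance under Brownian motion); the diagonal holds
#' root-to-tip distances. Computed with [ape::vcv.phylo()]. Trees need
#' not be ultrametric (e.g. an ML tree from SNPs); no clock rescaling is
#' applied. Optional rescaling divides G by its mean diagonal so that the
#' phylogenetic and residual variance components share a scale.
#'
#' @param tree An [ape::phylo] object, a newick string, or a path to a
#'   newick file.
#' @param tips Optional character vector: keep only these tips (e.g. to
#'   prune an outgroup).
#' @param rescale Divide G by its mean diagonal (`"unit_diag_mean"`) or
#'   leave as is (`"none"`, default)?
#' @return A symmetric positive semi-definite matrix with tip names as
#'   dimnames and attributes `rescale` and `scale_factor`.
#' @examples
#' phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' @export
phylo_covariance <- function(tree, tips = NULL,
                             rescale = c("none", "unit_diag_mean")) {
  rescale <- match.arg(rescale)
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths; covariance undefined")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort("tree has duplicate tip names")
  }
  if (!is.null(tips)) {
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) {
      abort(sprintf("tips not in tree: %s", paste(missing, collapse = ", ")))
    }
    tree <- ape::keep.tip(tree, tips)
  }
  G <- ape::vcv.phylo(tree)
  sf <- 1
  if (rescale == "unit_diag_mean") {
    sf <- mean(diag(G))
    G <- G / sf
  }
  structure(G, rescale = rescale, scale_factor = sf)
}

# Profile log-likelihood machinery: after one symmetric eigendecomposition
# of G* (G rescaled to unit mean diagonal), every mixing ratio h gives
# weights 1 / (h * e + 1 - h) and closed-form GLS mean and variance.
herit_workspace <- function(trait, G) {
  if (is.data.frame(trait)) {
    trait <- setNames(trait$value, trait$tip)
  }
  if (!is.null(names(trait))) {
    missing <- setdiff(rownames(G), names(trait))
    if (length(missing)) {
      abort(sprintf("trait missing for tips: %s",
                    paste(missing, collapse = ", ")))
    }
    trait <- trait[rownames(G)]
  }
  n <- length(trait)
  if (n != nrow(G)) abort("trait length must match G dimension")
  if (n < 4L) abort("need at least 4 tips")
  if (any(is.na(trait))) abort("trait contains missing values")
  if (var(trait) == 0) abort("trait is constant; heritability undefined")
  scale_factor <- mean(diag(G))
  eig <- eigen(G / scale_factor, symmetric = TRUE)
  e <- pmax(eig$values, 0)
  Q <- eig$vectors
  list(
    n = n, e = e, Q = Q,
    yt = as.numeric(crossprod(Q, trait)),
    ot = as.numeric(crossprod(Q, rep(1, n))),
    h_upper = if (min(e) < 1e-10) 1 - 1e-8 else 1,
    trait = trait, scale_factor = scale_factor
  )
}

herit_profile <- function(ws, h) {
  d <- h * ws$e + (1 - h)
  w <- 1 / d
  mu <- sum(w * ws$ot * ws$yt) / sum(w * ws$ot^2)
  r <- ws$yt - mu * ws$ot
  s2 <- sum(w * r^2) / ws$n
  ll <- -0.5 * (ws$n * log(2 * pi) + ws$n * log(s2) + sum(log(d)) + ws$n)
  list(h = h, mu = mu, s2 = s2, loglik = ll)
}

herit_fit_core <- function(ws, grid_n = 101L, tol = 1e-6) {
  grid <- seq(0, ws$h_upper, length.out = grid_n)
  ll <- vapply(grid, function(h) herit_profile(ws, h)$loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  opt <- optimize(function(h) herit_profile(ws, h)$loglik,
                  interval = c(lo, hi), maximum = TRUE, tol = tol)
  cand <- list(herit_profile(ws, opt$maximum),
               herit_profile(ws, grid[i]))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "loglik"))]]
  best$flat <- (max(ll) - min(ll)) < 1e-4
  best
}

#' Phylogenetic heritability of a trait under Brownian motion
#'
#' Fits, by maximum likelihood, the model
#' `trait ~ Normal(mu * 1, sigma2_phylo * G + sigma2_resid * I)` and
#' reports the phylogenetic heritability
#' `H2 = sigma2_phylo / (sigma2_phylo + sigma2_resid)` — the fraction of
#' among-tip trait variance attributable to shared ancestry. Internally G
#' is rescaled to unit mean diagonal so the two components share a scale,
#' and the likelihood is profiled over the mixing ratio
#' `h = H2` on `[0, 1]` (grid search plus local refinement, tolerance
#' 1e-6); the total variance and mean have closed-form solutions given
#' h. `H2` is invariant to affine transforms of the trait and, with the
#' internal rescaling, to multiplying all branch lengths by a constant.
#'
#' @param trait Named numeric vector (names = tip labels), or a data
#'   frame with columns `tip` and `value`.
#' @param G Phylogenetic covariance matrix from [phylo_covariance()].
#' @param metric_name Optional label stored in the result.
#' @param grid_n Number of initial grid points on `[0, 1]`.
#' @param tol Convergence tolerance of the local refinement.
#' @return A `phylo_herit` object (list) with elements `h2`,
#'   `sigma2_phylo`, `sigma2_resid`, `mu`, `loglik`, `n`, `flat`
#'   (flat-likelihood flag), `metric_name`. Supports [tidy()] and
#'   [glance()].
#' @export
estimate_heritability <- function(trait, G, metric_name = NA_character_,
                                  grid_n = 101L, tol = 1e-6) {
  ws <- herit_workspace(trait, G)
  best <- herit_fit_core(ws, grid_n, tol)
  h <- min(max(best$h, 0), 1)
  structure(
    list(
      metric_name = metric_name,
      h2 = h,
      sigma2_phylo = best$s2 * h / ws$scale_factor,
      sigma2_resid = best$s2 * (1 - h),
      mu = best$mu,
      loglik = best$loglik,
      n = ws$n,
      flat = best$flat
    ),
    class = "phylo_herit"
  )
}

#' @export
print.phylo_herit <- function(x, ...) {
  cat(sprintf(
    "<phylo_herit>%s H2 = %.3f (sigma2_phylo = %.4g, sigma2_resid = %.4g), n = %d, logLik = %.2f%s\n",
    if (is.na(x$metric_name)) "" else paste0(" ", x$metric_name),
    x$h2, x$sigma2_phylo, x$sigma2_resid, x$n, x$loglik,
    if (x$flat) " [flat likelihood]" else ""
  ))
  invisible(x)
}

#' Permutation p-value for phylogenetic heritability
#'
#' Shuffles trait values across the tree tips, re-estimates H2 on each
#' permuted dataset, and reports the one-sided empirical p-value
#' `p = (1 + #permutations with H2 >= observed) / (n_perm + 1)`.
#' Deterministic given `seed`.
#'
#' @inheritParams estimate_heritability
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A tibble with `metric_name`, `h2_observed`, `p_value`,
#'   `n_perm`, `seed`; the permuted H2 values are attached as attribute
#'   `h2_perm`.
#' @export
permutation_pvalue <- function(trait, G, n_perm = 1000, seed = NULL,
                               metric_name = NA_character_) {
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  ws <- herit_workspace(trait, G)
  obs <- herit_fit_core(ws)$h
  y <- unname(ws$trait)
  h2_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    wsp <- ws
    wsp$yt <- as.numeric(crossprod(ws$Q, sample(y)))
    herit_fit_core(wsp)$h
  }, numeric(1)))
  p <- (1 + sum(h2_perm >= obs)) / (n_perm + 1)
  structure(
    tibble(
      metric_name = metric_name, h2_observed = obs, p_value = p,
      n_perm = as.integer(n_perm), seed = seed %||% NA_integer_
    ),
    h2_perm = h2_perm
  )
}
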