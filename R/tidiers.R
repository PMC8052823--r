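#' Tidy a phylogenetic heritability fit
#'
#' @param x A `phylo_herit` object.
#' @param ... Ignored.
#' @return A tibble with one row per estimated quantity (`term`,
#'   `estimate`).
#' @exportS3Method generics::tidy
tidy.phylo_herit <- function(x, ...) {
  tibble(
    term = c("h2", "sigma2_phylo", "sigma2_resid", "mu"),
    estimate = c(x$h2, x$sigma2_phylo, x$sigma2_resid, x$mu)
  )
}

#' Glance at a phylogenetic heritability fit
#'
#' @param x A `phylo_herit` object.
#' @param ... Ignored.
#' @return A one-row tibble: `h2`, `logLik`, `n`, `flat`.
#' @exportS3Method generics::glance
glance.phylo_herit <- function(x, ...) {
  tibble(h2 = x$h2, logLik = x$loglik, n = x$n, flat = x$flat)
}

#' Tidy a variance partition
#'
#' @param x A `variance_partition` object.
#' @param ... Ignored.
#' @return The partition as a plain tibble (`term`, `df`, `sum_sq`,
#'   `percent_variance`, `statistic`, `p_value`).
#' @exportS3Method generics::tidy
tidy.variance_partition <- function(x, ...) {
  as_tibble(x)
}
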