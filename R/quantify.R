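#' Normalized frequencies of a satellite's constituent k-mers
#'
#' Joins a GC-normalized profile onto the distinct canonical k-mers of a
#' consensus decomposition. Duplicate canonical k-mers within the
#' consensus (internal periodicity) contribute once. Missing values
#' (k-mer unobserved in the library) are carried, not dropped.
#'
#' @param profile A `norm_profile` from [normalize_profile()].
#' @param cks A `consensus_kmer_set` with the same k.
#' @return Tibble with columns `kmer` (distinct canonical constituent
#'   k-mers) and `normalized`.
#' @export
satellite_kmer_frequencies <- function(profile, cks) {
  stopifnot(inherits(profile, "norm_profile"),
            inherits(cks, "consensus_kmer_set"))
  if (!identical(attr(profile, "k"), attr(cks, "k"))) {
    abort("`profile` and `cks` were built with different k")
  }
  kmers <- unique(cks$canonical)
  tibble(
    kmer = kmers,
    normalized = profile$normalized[match(kmers, profile$kmer)]
  )
}

#' Estimate satellite copy number from constituent k-mer frequencies
#'
#' The estimator is the median of the normalized (log10) frequencies of
#' the consensus repeat's constituent k-mers; copy number is `10^median`.
#' A median of 5 means an estimated 10^5 copies of the repeat in the
#' genome. Average array length per chromosome is
#' `copies * L / n_chromosomes` (house mouse default: 2n = 40
#' chromosomes, each with one telocentric centromere).
#'
#' Missing values (k-mers unobserved in the library) are excluded from
#' the median; when more than `max_missing` of the constituent k-mers are
#' missing the estimate is flagged `below_detection` and copy number is
#' `NA`.
#'
#' @param freqs Tibble from [satellite_kmer_frequencies()] (or a numeric
#'   vector of normalized log10 values, possibly containing `NA`).
#' @param unit_length Satellite repeat unit length L in bp (minor 120,
#'   major 234).
#' @param n_chromosomes Number of chromosomes sharing the genome-wide
#'   array (default 40).
#' @param satellite Optional satellite name recorded in the result.
#' @param max_missing Missing fraction above which the estimate is
#'   flagged below detection (default 0.5).
#' @return A one-row tibble: `satellite`, `n_kmers`, `n_missing`,
#'   `median_normalized`, `copies`, `per_chromosome_bp`,
#'   `below_detection`.
#' @examples
#' estimate_copy_number(rep(5, 11), unit_length = 234) # 1e5 copies
#' @export
estimate_copy_number <- function(freqs, unit_length, n_chromosomes = 40,
                                 satellite = NA_character_,
                                 max_missing = 0.5) {
  values <- if (is.data.frame(freqs)) freqs$normalized else as.numeric(freqs)
  n <- length(values)
  if (n == 0L) abort("no constituent k-mer values supplied")
  n_missing <- sum(is.na(values))
  below <- n_missing / n > max_missing || n_missing == n
  med <- if (n_missing < n) median(values, na.rm = TRUE) else NA_real_
  copies <- if (below) NA_real_ else 10^med
  tibble(
    satellite = satellite,
    n_kmers = n, n_missing = n_missing,
    median_normalized = med,
    copies = copies,
    per_chromosome_bp = copies * unit_length / n_chromosomes,
    below_detection = below
  )
}

#' Fold range of copy-number estimates
#'
#' `max(x) / min(x)`; the headline contrast between the largest and
#' smallest satellite arrays in a panel of genomes.
#'
#' @param x Positive copy numbers.
#' @return A single ratio.
#' @examples
#' fold_range(c(260220, 1320)) # ~197
#' @export
fold_range <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x <= 0)) abort("all copy numbers must be > 0")
  max(x) / min(x)
}

#' Rank k-mers by their frequency variance across samples
#'
#' For each k-mer, computes the variance (n - 1 denominator) of
#' depth-standardized frequencies `F_s = count_s / standardizer_s` across
#' samples, where the standardizer defaults to
#' `total_read_bases / genome_size` (sequencing depth). k-mers absent
#' from a sample contribute `F_s = 0`. The most variable k-mers across a
#' diverse panel are strongly enriched for satellite repeats, whose copy
#' number differs between genomes.
#'
#' @param tables List of `kmer_tbl` objects with identical k (one per
#'   sample).
#' @param top_n Number of top-variance k-mers to return (default 1000).
#' @param genome_size Genome size used to convert `total_read_bases` to
#'   depth (default 2.7e9, the house mouse genome); the ranking is
#'   invariant to any rescaling common to all samples.
#' @param standardizer Optional explicit per-sample divisor overriding
#'   the depth computation.
#' @return Tibble with columns `kmer`, `variance`, `rank` (top `top_n`,
#'   decreasing variance), plus per-sample standardized frequencies in a
#'   `freq` matrix attribute.
#' @export
kmer_variance_scan <- function(tables, top_n = 1000, genome_size = 2.7e9,
                               standardizer = NULL) {
  if (length(tables) < 2L) abort("need at least 2 samples")
  ks <- vapply(tables, attr, integer(1), "k")
  if (length(unique(ks)) != 1L) abort("all tables must share one k")
  if (is.null(standardizer)) {
    standardizer <- vapply(
      tables, function(t) attr(t, "total_read_bases") / genome_size,
      numeric(1)
    )
  }
  if (any(standardizer <= 0)) abort("standardizers must be positive")
  all_kmers <- sort(unique(unlist(lapply(tables, `[[`, "kmer"))))
  freq <- vapply(seq_along(tables), function(i) {
    cnt <- tables[[i]]$count[match(all_kmers, tables[[i]]$kmer)]
    cnt[is.na(cnt)] <- 0
    cnt / standardizer[i]
  }, numeric(length(all_kmers)))
  v <- apply(freq, 1L, var)
  ord <- order(-v, all_kmers)
  keep <- head(ord, top_n)
  structure(
    tibble(kmer = all_kmers[keep], variance = v[keep],
           rank = seq_along(keep)),
    k = ks[1L],
    freq = {
      m <- freq[keep, , drop = FALSE]
      rownames(m) <- all_kmers[keep]
      colnames(m) <- names(tables) %||% paste0("sample", seq_along(tables))
      m
    },
    class = c("kmer_variance_scan", class(tibble()))
  )
}

#' Partition response variance across ordered categorical factors
#'
#' Sequential (type-I) ANOVA decomposition: the percent of total variance
#' attributed to each factor is its sequential sum of squares divided by
#' the total sum of squares. Used to ask, e.g., how much of the variation
#' in satellite k-mer frequencies is due to strain identity versus
#' sequencing library, or to subspecies versus population versus
#' individual.
#'
#' @param data Data frame holding the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names; order matters
#'   (type-I sums of squares are sequential).
#' @return A `variance_partition` tibble: `term`, `df`, `sum_sq`,
#'   `percent_variance`, `statistic` (F), `p_value`, including a
#'   `Residuals` row. Percents sum to 100.
#' @export
partition_variance <- function(data, response, factors) {
  stopifnot(is.data.frame(data), all(c(response, factors) %in% names(data)))
  data <- as.data.frame(data)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2L) {
      warn(sprintf("factor `%s` has a single level; it explains 0%%", f))
    }
  }
  keep <- factors[vapply(factors, function(f) nlevels(data[[f]]) > 1L,
                         logical(1))]
  if (length(keep) == 0L) abort("no factor has more than one level")
  form <- stats::reformulate(keep, response)
  fit <- aov(form, data = data)
  an <- as.data.frame(anova(fit))
  total_ss <- sum(an[["Sum Sq"]])
  out <- tibble(
    term = rownames(an),
    df = an$Df,
    sum_sq = an[["Sum Sq"]],
    percent_variance = 100 * an[["Sum Sq"]] / total_ss,
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  )
  dropped <- setdiff(factors, keep)
  if (length(dropped)) {
    out <- bind_rows(out, tibble(
      term = dropped, df = 0L, sum_sq = 0, percent_variance = 0,
      statistic = NA_real_, p_value = NA_real_
    ))
  }
  structure(out, response = response, factors = factors,
            class = c("variance_partition", class(tibble())))
}
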