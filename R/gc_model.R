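#' Select single-copy reference k-mers for GC-model fitting
#'
#' Samples `n` k-mers uniformly without replacement from those occurring
#' exactly once in a reference k-mer table. Their observed counts in a
#' sequencing library define the expected coverage of a single-copy locus
#' at each GC level — the baseline every other k-mer is normalized
#' against. The workflow default panel size is 100,000.
#'
#' @param reference_counts A `kmer_tbl` built from a reference genome
#'   (see [count_reference_kmers()]), not from reads.
#' @param n Panel size; if fewer singleton k-mers exist, all are returned
#'   with a warning.
#' @param seed Integer seed making the sample reproducible.
#' @return A tibble with columns `kmer` and `gc_count`, class
#'   `kmer_panel`, attributes `k`, `panel_size`, `seed`.
#' @export
select_unique_kmers <- function(reference_counts, n = 1e5, seed = NULL) {
  stopifnot(inherits(reference_counts, "kmer_tbl"))
  k <- attr(reference_counts, "k")
  singles <- reference_counts$kmer[reference_counts$count == 1]
  if (length(singles) == 0L) {
    abort("no k-mers occur exactly once in the reference")
  }
  if (length(singles) < n) {
    warn(sprintf(
      "only %d singleton k-mers available (requested %d); using all",
      length(singles), as.integer(n)
    ))
    picked <- singles
  } else {
    picked <- with_seed(seed, sample(singles, n))
  }
  picked <- sort(picked)
  structure(
    tibble(kmer = picked, gc_count = gc_count(picked)),
    k = k, panel_size = length(picked), seed = seed,
    class = c("kmer_panel", class(tibble()))
  )
}

#' Fit the per-library GC-bias model
#'
#' Models the observed count of single-copy (panel) k-mers as a function
#' of their GC content with LOESS (default span 0.4), then evaluates the
#' fit at every integer GC level 0..k. The prediction at a level is the
#' expected count of a single-copy k-mer with that GC content in this
#' library — the "amplification" baseline. Levels outside the observed GC
#' range are filled by nearest-level extrapolation and flagged. All
#' predictions are floored at a small positive `floor` to guard against
#' LOESS undershoot at sparse extremes.
#'
#' Panel k-mers unobserved in the library enter the fit with count 0 by
#' default (`include_zeros = FALSE` drops them instead).
#'
#' @param library A `kmer_tbl` for one sequencing library.
#' @param panel A `kmer_panel` from [select_unique_kmers()] with matching
#'   k.
#' @param span LOESS span (fraction of points in each local fit).
#' @param include_zeros Include panel k-mers with zero observed count?
#' @param floor Positive lower bound applied to predictions (counts).
#' @return A `gc_model`: tibble with columns `gc_count`, `gc_frac`,
#'   `predicted`, `n_panel`, `extrapolated`; attributes `k`, `span`,
#'   `library_id`.
#' @export
fit_gc_model <- function(library, panel, span = 0.4, include_zeros = TRUE,
                         floor = 0.01) {
  stopifnot(inherits(library, "kmer_tbl"), inherits(panel, "kmer_panel"))
  k <- attr(library, "k")
  if (!identical(k, attr(panel, "k"))) {
    abort("`library` and `panel` were built with different k")
  }
  obs <- library$count[match(panel$kmer, library$kmer)]
  obs[is.na(obs)] <- 0
  dat <- tibble(gc = panel$gc_count, count = obs)
  if (!include_zeros) dat <- filter(dat, .data$count > 0)
  if (length(unique(dat$gc)) < 2L) {
    abort("fewer than 2 distinct GC levels among panel k-mers; fit undefined")
  }
  dat$gc_frac <- dat$gc / k
  # GC levels are discrete (k + 1 values), which makes the local fits
  # rank-deficient in a benign way; muffle only those warnings.
  quiet_loess <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("pseudoinverse|neighborhood radius|reciprocal condition|singularities",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  fit <- quiet_loess(loess(count ~ gc_frac, data = dat, span = span,
                           degree = 2, family = "gaussian",
                           control = stats::loess.control(surface = "direct")))
  levels <- 0:k
  frac <- levels / k
  inside <- frac >= min(dat$gc_frac) & frac <= max(dat$gc_frac)
  pred <- rep(NA_real_, k + 1L)
  pred[inside] <- quiet_loess(
    predict(fit, newdata = data.frame(gc_frac = frac[inside]))
  )
  # nearest populated level fills the outside
  if (any(!inside)) {
    in_idx <- which(inside)
    for (i in which(!inside)) {
      pred[i] <- pred[in_idx[which.min(abs(in_idx - i))]]
    }
  }
  pred <- pmax(pred, floor)
  n_panel <- tabulate(dat$gc + 1L, nbins = k + 1L)
  structure(
    tibble(
      gc_count = levels, gc_frac = frac, predicted = pred,
      n_panel = n_panel, extrapolated = !inside
    ),
    k = k, span = span, floor = floor,
    library_id = attr(library, "library_id"),
    panel_data = dat,
    class = c("gc_model", class(tibble()))
  )
}

#' Normalize an observed k-mer count by its GC-predicted baseline
#'
#' The normalized value is `log10(observed / predicted)`: 0 for a
#' single-copy locus, 2 for a locus present in ~100 copies. A zero
#' observed count returns `NA` (missing), never `-Inf`; missingness is
#' tracked downstream rather than poisoning medians.
#'
#' @param observed Non-negative observed counts.
#' @param predicted Positive LOESS-predicted single-copy counts.
#' @return Numeric vector of log10 ratios (`NA` where `observed == 0`).
#' @examples
#' normalize_count(1000, 10) # 2
#' @export
normalize_count <- function(observed, predicted) {
  if (any(predicted <= 0, na.rm = TRUE)) {
    abort("`predicted` must be strictly positive")
  }
  if (any(observed < 0, na.rm = TRUE)) abort("`observed` must be >= 0")
  out <- log10(observed / predicted)
  out[observed == 0] <- NA_real_
  out
}

#' GC-normalized k-mer profile for a set of query k-mers
#'
#' Looks up the raw count of each query k-mer in a library, keys it by
#' its GC level and divides by the library's LOESS-predicted single-copy
#' count at that level (on the log10 scale). Queries unobserved in the
#' library get `NA`.
#'
#' @param library A `kmer_tbl` for the library the model was fitted on.
#' @param model A `gc_model` fitted from the same library.
#' @param query_kmers Character vector of canonical k-mers to normalize.
#' @return A `norm_profile`: tibble with columns `kmer`, `gc_count`,
#'   `raw`, `normalized`; attributes `k`, `sample_id`, `library_id`.
#' @export
normalize_profile <- function(library, model, query_kmers) {
  stopifnot(inherits(library, "kmer_tbl"), inherits(model, "gc_model"))
  k <- attr(library, "k")
  if (!identical(k, attr(model, "k"))) {
    abort("`library` and `model` were built with different k")
  }
  query_kmers <- unique(as.character(query_kmers))
  if (length(query_kmers) &&
      !all(nchar(query_kmers) == k)) {
    abort(sprintf("query k-mers must all have length k = %d", k))
  }
  gc <- gc_count(query_kmers)
  raw <- library$count[match(query_kmers, library$kmer)]
  raw[is.na(raw)] <- 0
  predicted <- model$predicted[gc + 1L]
  structure(
    tibble(
      kmer = query_kmers, gc_count = gc, raw = raw,
      normalized = normalize_count(raw, predicted)
    ),
    k = k,
    sample_id = attr(library, "sample_id"),
    library_id = attr(library, "library_id"),
    class = c("norm_profile", class(tibble()))
  )
}

#' Serialize / read a GC model as TSV plus JSON metadata
#'
#' @param x A `gc_model`.
#' @param path Output TSV path (`gc_count`, `predicted`, ...).
#' @return `path` invisibly (writer); a `gc_model` (reader).
#' @export
write_gc_model <- function(x, path) {
  stopifnot(inherits(x, "gc_model"))
  readr::write_tsv(as_tibble(x), path)
  jsonlite::write_json(
    attributes(x)[c("k", "span", "floor", "library_id")],
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_gc_model
#' @export
read_gc_model <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ddddl", progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    tbl,
    k = as.integer(meta$k), span = meta$span, floor = meta$floor,
    library_id = meta$library_id,
    class = c("gc_model", class(tibble()))
  )
}
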