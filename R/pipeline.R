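#' Build a pipeline run configuration
#'
#' Collects the tunable parameters of the workflow with their defaults;
#' `h_max` follows the relaxed-distance convention (2 for k = 15, 5 for
#' k = 31) unless given. Coordinates are 1-based inclusive on consensus
#' sequences everywhere. The configuration is hashed and the hash stamped
#' on every output file for provenance.
#'
#' @param fastq Named character vector of FASTQ paths; names are sample
#'   ids (one library per entry).
#' @param consensus_fasta Path to a FASTA of satellite consensus
#'   sequences (e.g. minor 120 bp, major 234 bp).
#' @param reference_fasta Path to a reference genome FASTA used to select
#'   single-copy k-mers for the GC model.
#' @param out_dir Output directory.
#' @param k k-mer length (default 31).
#' @param h_max Relaxed-match distance cap (default by k).
#' @param span LOESS span for the GC model.
#' @param min_identity Mapping identity threshold for the CDI.
#' @param n_chromosomes Chromosomes sharing the array (default 40).
#' @param panel_size Unique-k-mer panel size (default 100,000).
#' @param top_n Variable-k-mer scan size (default 1000).
#' @param n_perm Permutations for heritability p-values.
#' @param pairs_per_position_cap CDI pair subsampling cap.
#' @param tree Optional newick path for the heritability stage.
#' @param circular Treat consensus units as circular (default TRUE).
#' @param seed Master seed for all stochastic steps.
#' @return A `censat_config` list with a `hash` element.
#' @export
run_config <- function(fastq, consensus_fasta, reference_fasta, out_dir,
                       k = 31, h_max = NULL, span = 0.4,
                       min_identity = 0.8, n_chromosomes = 40,
                       panel_size = 1e5, top_n = 1000, n_perm = 1000,
                       pairs_per_position_cap = 200, tree = NULL,
                       circular = TRUE, seed = 1) {
  k <- check_k(k)
  cfg <- list(
    fastq = fastq, consensus_fasta = consensus_fasta,
    reference_fasta = reference_fasta, out_dir = out_dir,
    k = k, h_max = default_h_max(k, h_max), span = span,
    min_identity = min_identity, n_chromosomes = n_chromosomes,
    panel_size = panel_size, top_n = top_n, n_perm = n_perm,
    pairs_per_position_cap = pairs_per_position_cap,
    tree = tree, circular = circular, seed = seed
  )
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "censat_config")
}

write_stamped_tsv <- function(x, path, hash) {
  writeLines(sprintf("# censat_config %s", hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

check_input_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("%s not found: %s", what, path %||% "<missing>"))
  }
  invisible(path)
}

run_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full satellite quantification pipeline
#'
#' Executes count -> GC-normalize -> quantify -> CDI -> polymorphism
#' landscape (-> heritability when a tree is configured) for every
#' configured library, writing TSV outputs (stamped with the
#' configuration hash) and a machine-readable JSON summary to
#' `out_dir`.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with elements `copy_number`, `cdi`,
#'   `landscape`, and (if a tree was given) `heritability`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "censat_config"))
  for (f in config$fastq) check_input_file(f, "FASTQ file")
  check_input_file(config$consensus_fasta, "consensus FASTA")
  check_input_file(config$reference_fasta, "reference FASTA")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cons_seqs <- run_stage("load_consensus", read_fasta(config$consensus_fasta))
  consensuses <- purrr::imap(cons_seqs, function(s, nm) {
    satellite_consensus(nm, s, circular = config$circular)
  })
  ckss <- purrr::map(consensuses, consensus_kmer_set, k = config$k)

  panel <- run_stage("reference_panel", {
    ref <- count_reference_kmers(config$reference_fasta, config$k)
    select_unique_kmers(ref, n = config$panel_size,
                        seed = child_seed(config$seed, "panel"))
  })

  samples <- names(config$fastq) %||% paste0("sample", seq_along(config$fastq))
  per_sample <- purrr::map2(config$fastq, samples, function(fq, sid) {
    tab <- run_stage("count", count_library(fq, config$k, sample_id = sid))
    model <- run_stage("gc_model", fit_gc_model(tab, panel,
                                                span = config$span))
    write_gc_model(model, file.path(config$out_dir,
                                    sprintf("gc_model_%s.tsv", sid)))
    reads <- read_fastq(fq)

    cn <- purrr::imap(ckss, function(cks, nm) {
      prof <- normalize_profile(tab, model, unique(cks$canonical))
      freqs <- satellite_kmer_frequencies(prof, cks)
      estimate_copy_number(freqs, unit_length = attr(cks, "L"),
                           n_chromosomes = config$n_chromosomes,
                           satellite = nm)
    }) |> bind_rows() |> mutate(sample = sid, .before = 1)

    aln <- run_stage("cdi_map",
                     map_reads_to_consensus(reads, consensuses,
                                            config$min_identity))
    cdi <- run_stage("cdi", centromere_diversity_index(
      aln, reads, consensuses,
      pairs_per_position_cap = config$pairs_per_position_cap,
      seed = child_seed(config$seed, paste0("cdi_", sid))
    )) |> mutate(sample = sid, .before = 1)

    land <- purrr::imap(ckss, function(cks, nm) {
      pm <- run_stage("landscape",
                      build_polymorphism_matrix(tab, cks, config$h_max))
      mutate(as_tibble(pm), sample = sid, satellite = nm, .before = 1)
    }) |> bind_rows()

    list(copy_number = cn, cdi = cdi, landscape = land)
  })

  out <- list(
    copy_number = bind_rows(purrr::map(per_sample, "copy_number")),
    cdi = bind_rows(purrr::map(per_sample, "cdi")),
    landscape = bind_rows(purrr::map(per_sample, "landscape"))
  )

  if (!is.null(config$tree) && length(samples) >= 4L) {
    out$heritability <- run_stage("heritability", {
      G <- phylo_covariance(config$tree, tips = samples)
      purrr::map(names(ckss), function(nm) {
        traits <- list(
          copy_number = setNames(
            log10(out$copy_number$copies[out$copy_number$satellite == nm]),
            out$copy_number$sample[out$copy_number$satellite == nm]),
          cdi = setNames(out$cdi$cdi[out$cdi$satellite == nm],
                         out$cdi$sample[out$cdi$satellite == nm])
        )
        purrr::imap(traits, function(tr, metric) {
          fit <- estimate_heritability(tr, G,
                                       metric_name = paste(nm, metric))
          pv <- permutation_pvalue(tr, G, n_perm = config$n_perm,
                                   seed = child_seed(config$seed, "perm"),
                                   metric_name = paste(nm, metric))
          tibble(satellite = nm, metric = metric, h2 = fit$h2,
                 sigma2_phylo = fit$sigma2_phylo,
                 sigma2_resid = fit$sigma2_resid,
                 p_value = pv$p_value, n_perm = pv$n_perm)
        }) |> bind_rows()
      }) |> bind_rows()
    })
  }

  write_stamped_tsv(out$copy_number,
                    file.path(config$out_dir, "copy_number.tsv"),
                    config$hash)
  write_stamped_tsv(out$cdi, file.path(config$out_dir, "cdi.tsv"),
                    config$hash)
  write_stamped_tsv(out$landscape,
                    file.path(config$out_dir, "polymorphism.tsv"),
                    config$hash)
  if (!is.null(out$heritability)) {
    write_stamped_tsv(out$heritability,
                      file.path(config$out_dir, "heritability.tsv"),
                      config$hash)
  }
  jsonlite::write_json(
    list(
      config = config[setdiff(names(config), "hash")],
      hash = config$hash,
      n_samples = length(samples),
      satellites = names(ckss),
      copy_number = out$copy_number,
      cdi = out$cdi
    ),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(out)
}

# --- minimal command-line front end -----------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) abort(sprintf("unexpected argument: %s", a))
    key <- gsub("-", "_", substring(a, 3L))
    val <- if (i == length(args) || startsWith(args[i + 1L], "--")) {
      i <- i + 1L
      TRUE
    } else {
      i <- i + 2L
      args[i - 1L]
    }
    out[[key]] <- if (length(out[[key]])) c(out[[key]], val) else val
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `count`, `quantify`, `cdi`,
#' `landscape`, `phyloh` and `run` over the package's functions. This is
#' the engine behind the `inst/cli/censat.R` script:
#' `Rscript censat.R <subcommand> --key value ...`. Coordinates in all
#' outputs are 1-based inclusive on consensus sequences.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Exit status (0 on success), invisibly.
#' @export
censat_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: censat <subcommand> [--key value ...]",
    "subcommands:",
    "  simulate  --out-dir D [--seed S --copies C --rate R --depth X",
    "            --read-length L --background B]",
    "  count     --fastq F --k K --out OUT.tsv [--sample S]",
    "  quantify  --fastq F --reference REF.fa --consensus CONS.fa",
    "            [--k K --n-chromosomes N --panel-size P --seed S] --out OUT.tsv",
    "  cdi       --fastq F --consensus CONS.fa [--min-identity I --cap C",
    "            --seed S] --out OUT.tsv",
    "  landscape --fastq F --consensus CONS.fa [--k K --h-max H] --out OUT.tsv",
    "  phyloh    --tree T.nwk --traits TR.tsv (columns tip, value)",
    "            [--n-perm N --seed S] --out OUT.tsv",
    "  run       --fastq F [--fastq F2 ...] --reference REF.fa",
    "            --consensus CONS.fa --out-dir D [--k K --seed S]",
    sep = "\n"
  )
  if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
    message(usage)
    return(invisible(0L))
  }
  cmd <- args[1L]
  opts <- parse_cli_args(args[-1L])
  k <- as.integer(cli_num(opts, "k", 31))
  seed <- as.integer(cli_num(opts, "seed", 1))

  load_consensuses <- function() {
    purrr::imap(read_fasta(opts$consensus),
                function(s, nm) satellite_consensus(nm, s))
  }
  quantify_one <- function(tab) {
    ref <- count_reference_kmers(opts$reference, k)
    panel <- select_unique_kmers(ref, n = cli_num(opts, "panel_size", 1e5),
                                 seed = seed)
    model <- fit_gc_model(tab, panel)
    purrr::imap(load_consensuses(), function(cons, nm) {
      cks <- consensus_kmer_set(cons, k)
      prof <- normalize_profile(tab, model, unique(cks$canonical))
      estimate_copy_number(
        satellite_kmer_frequencies(prof, cks), unit_length = cons$L,
        n_chromosomes = cli_num(opts, "n_chromosomes", 40), satellite = nm
      )
    }) |> bind_rows()
  }

  switch(cmd,
    simulate = {
      fx <- scenario_fixtures(
        seed = seed, depth = cli_num(opts, "depth", 20),
        read_length = cli_num(opts, "read_length", 100),
        background_length = cli_num(opts, "background", 50000)
      )
      dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(c(minor_like = fx$consensus$sequence),
                  file.path(opts$out_dir, "consensus.fasta"))
      for (nm in c("inbred_like", "wild_like")) {
        write_fasta(setNames(fx[[nm]]$genome$sequence, nm),
                    file.path(opts$out_dir, paste0(nm, "_genome.fasta")))
        write_fastq(fx[[nm]]$reads,
                    file.path(opts$out_dir, paste0(nm, "_reads.fastq")))
      }
      jsonlite::write_json(
        list(seed = seed,
             inbred_like = list(copies = fx$inbred_like$copies,
                                rate = fx$inbred_like$rate),
             wild_like = list(copies = fx$wild_like$copies,
                              rate = fx$wild_like$rate)),
        file.path(opts$out_dir, "truth.json"), auto_unbox = TRUE
      )
    },
    count = {
      tab <- count_library(opts$fastq, k,
                           sample_id = opts$sample %||% NA_character_)
      write_kmer_tbl(tab, opts$out)
    },
    quantify = {
      tab <- count_library(opts$fastq, k)
      readr::write_tsv(quantify_one(tab), opts$out)
    },
    cdi = {
      reads <- read_fastq(opts$fastq)
      consensuses <- load_consensuses()
      aln <- map_reads_to_consensus(reads, consensuses,
                                    cli_num(opts, "min_identity", 0.8))
      res <- centromere_diversity_index(
        aln, reads, consensuses,
        pairs_per_position_cap = cli_num(opts, "cap", 200), seed = seed
      )
      readr::write_tsv(res, opts$out)
    },
    landscape = {
      tab <- count_library(opts$fastq, k)
      res <- purrr::imap(load_consensuses(), function(cons, nm) {
        pm <- build_polymorphism_matrix(
          tab, consensus_kmer_set(cons, k),
          h_max = if (is.null(opts$h_max)) NULL else as.integer(opts$h_max)
        )
        mutate(as_tibble(pm), satellite = nm, .before = 1)
      }) |> bind_rows()
      readr::write_tsv(res, opts$out)
    },
    phyloh = {
      tr <- readr::read_tsv(opts$traits, col_types = "cd", progress = FALSE)
      G <- phylo_covariance(opts$tree, tips = tr$tip)
      trait <- setNames(tr$value, tr$tip)
      fit <- estimate_heritability(trait, G)
      pv <- permutation_pvalue(trait, G,
                               n_perm = cli_num(opts, "n_perm", 1000),
                               seed = seed)
      readr::write_tsv(tibble(
        h2 = fit$h2, sigma2_phylo = fit$sigma2_phylo,
        sigma2_resid = fit$sigma2_resid, mu = fit$mu,
        loglik = fit$loglik, p_value = pv$p_value, n_perm = pv$n_perm,
        seed = seed
      ), opts$out)
    },
    run = {
      cfg <- run_config(
        fastq = setNames(opts$fastq,
                         opts$sample %||%
                           paste0("sample", seq_along(opts$fastq))),
        consensus_fasta = opts$consensus,
        reference_fasta = opts$reference,
        out_dir = opts$out_dir, k = k, seed = seed,
        n_perm = cli_num(opts, "n_perm", 1000), tree = opts$tree
      )
      run_pipeline(cfg)
    },
    abort(sprintf("unknown subcommand '%s'\n%s", cmd, usage))
  )
  invisible(0L)
}
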