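#' Configuration for an end-to-end screening run
#'
#' Exactly one of `proteins`, `contigs`, `genome` must be supplied, either
#' as a FASTA path or as a sequence-record `data.frame`.
#'
#' @param polymers character vector of target polymers.
#' @param proteins,contigs,genome the input (path or records).
#' @param reads optional SAM/BAM path (or alignment `data.frame`) of reads
#'   mapped against the candidate gene sequences, for abundance.
#' @param sensitive use the recall-oriented classifier mode.
#' @param high_confidence_threshold score threshold for the
#'   high-confidence flag (default 0.7).
#' @param benchmark_threshold positive-call threshold used in
#'   benchmarking (default 0.5).
#' @param cores worker count hint (scoring is sequential and
#'   deterministic regardless of the value).
#' @param gpu passed through to an external embedder as a hint; unused by
#'   the default embedder.
#' @param seed RNG seed for every stochastic step of the run.
#' @param sample_name sample label stamped on the report (defaults to the
#'   input file base name, or `"sample1"`).
#' @param output_dir where `summary.csv`, `hits.fasta`, `abundance.csv`
#'   are written.
#' @param min_aa_len minimum ORF length for nucleotide input.
#' @return a list of class `run_config`.
#' @export
run_config <- function(polymers, proteins = NULL, contigs = NULL,
                       genome = NULL, reads = NULL, sensitive = FALSE,
                       high_confidence_threshold = 0.7,
                       benchmark_threshold = 0.5, cores = 1L, gpu = FALSE,
                       seed = 42L, sample_name = NULL,
                       output_dir = tempfile("plastizymr_run"),
                       min_aa_len = 30L) {
  inputs <- list(proteins = proteins, contigs = contigs, genome = genome)
  set <- !vapply(inputs, is.null, logical(1))
  if (sum(set) != 1L) {
    stop("exactly one of proteins, contigs, genome must be given")
  }
  if (high_confidence_threshold <= 0 || high_confidence_threshold >= 1 ||
      benchmark_threshold <= 0 || benchmark_threshold >= 1) {
    stop("thresholds must be in (0, 1)")
  }
  mode <- names(inputs)[set]
  structure(list(polymers = polymers, input = inputs[[mode]],
                 input_mode = mode, reads = reads, sensitive = sensitive,
                 high_confidence_threshold = high_confidence_threshold,
                 benchmark_threshold = benchmark_threshold,
                 cores = as.integer(cores), gpu = gpu,
                 seed = as.integer(seed), sample_name = sample_name,
                 output_dir = output_dir, min_aa_len = as.integer(min_aa_len)),
            class = "run_config")
}

#' Bundle the reference resources for a screening run
#'
#' @param profiles named list (polymer -> calibrated `profile_hmm`).
#' @param pairwise_db named list (polymer -> seed sequence records) for
#'   polymers screened by pairwise alignment only.
#' @param models named list with elements `default` and/or `sensitive`,
#'   each a `plastizyme_classifier`.
#' @param embedder embedder contract used for classification.
#' @return a list of class `run_resources`.
#' @export
run_resources <- function(profiles = list(), pairwise_db = list(),
                          models = list(), embedder = default_embedder()) {
  structure(list(profiles = profiles, pairwise_db = pairwise_db,
                 models = models, embedder = embedder),
            class = "run_resources")
}

#' Run the full plastizyme screen
#'
#' Steps: gene calling (for nucleotide input), homology screen against the
#' per-polymer profiles (pairwise fallback where no profile exists), the
#' standard hit filters, embedding and per-polymer classification of the
#' survivors, optional read-based abundance, and report writing.
#'
#' @param config a [run_config()].
#' @param resources a [run_resources()].
#' @return a list with `summary` (the report `data.frame`), `hits`
#'   (protein records of filtered hits), paths of the written artifacts,
#'   and `stage_counts` (per-stage tallies).
#' @export
run_pipeline <- function(config, resources) {
  missing_res <- setdiff(config$polymers,
                         c(names(resources$profiles),
                           names(resources$pairwise_db)))
  if (length(missing_res)) {
    stop("no profile or seed set for polymer(s) ",
         paste(missing_res, collapse = ", "), "; available: ",
         paste(union(names(resources$profiles),
                     names(resources$pairwise_db)), collapse = ", "))
  }
  input <- config$input
  if (is.character(input)) {
    alph <- if (config$input_mode == "proteins") "protein" else "nucleotide"
    sample_name <- config$sample_name
    if (is.null(sample_name)) {
      sample_name <- sub("\\.[^.]*$", "", basename(input))
    }
    input <- read_fasta(input, alphabet = alph, sample = sample_name)
  } else {
    sample_name <- config$sample_name
    if (is.null(sample_name)) sample_name <- "sample1"
  }
  input$sample[is.na(input$sample)] <- sample_name

  set.seed(config$seed)
  genes <- call_genes(input, config$input_mode,
                      orf_params(min_aa_len = config$min_aa_len))
  n_called <- nrow(genes)

  # preprocess: trim terminal ambiguity codes, drop unembeddable proteins
  cleaned <- vapply(genes$seq, function(s) {
    tryCatch(preprocess_sequence(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(cleaned)
  n_dropped <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  genes$seq <- cleaned[keep]
  if (nrow(genes) == 0L) stop("no screenable proteins in input")

  db_size <- nrow(genes)
  hits <- list()
  for (polymer in config$polymers) {
    prof <- resources$profiles[[polymer]]
    if (!is.null(prof)) {
      if (is.null(prof$calibration)) {
        stop("profile for ", polymer, " is not calibrated")
      }
      for (i in seq_len(nrow(genes))) {
        hits[[length(hits) + 1L]] <-
          score_protein(prof, genes$seq[i], genes$id[i], db_size)
      }
    } else {
      targets <- resources$pairwise_db[[polymer]]
      for (i in seq_len(nrow(genes))) {
        h <- pairwise_search(genes[i, , drop = FALSE], targets, polymer)
        hits[[length(hits) + 1L]] <- h[1L, , drop = FALSE]  # best per polymer
      }
    }
  }
  hits <- do.call(rbind, hits)
  n_prefilter <- nrow(hits)
  hits <- filter_hits(hits)
  n_postfilter <- nrow(hits)

  hit_genes <- genes[genes$id %in% unique(hits$protein_id), , drop = FALSE]

  # classify survivors for polymers with a model
  ml_mode <- if (isTRUE(config$sensitive)) "sensitive" else "default"
  model <- resources$models[[ml_mode]]
  hits$ml_mode <- ""
  hits$ml_score <- NA_real_
  if (!is.null(model) && nrow(hit_genes) > 0L) {
    unsupported <- setdiff(intersect(config$polymers,
                                     unique(hits$polymer)),
                           model$polymers)
    if (length(unsupported)) {
      warning("classifier supports only ",
              paste(model$polymers, collapse = ", "),
              "; homology-only output for ",
              paste(unsupported, collapse = ", "))
    }
    emb <- embed_records(hit_genes, resources$embedder)
    scores <- predict_scores(model, emb)
    for (r in seq_len(nrow(hits))) {
      p <- hits$polymer[r]
      if (p %in% colnames(scores)) {
        hits$ml_mode[r] <- ml_mode
        hits$ml_score[r] <- scores[hits$protein_id[r], p]
      }
    }
  }
  hits$passes_high_confidence <- !is.na(hits$ml_score) &
    hits$ml_score > config$high_confidence_threshold
  hits$sample <- sample_name

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(config$output_dir, "summary.csv")
  summary_df <- write_summary(hits, summary_path)

  hits_fasta <- NULL
  if (nrow(hit_genes) > 0L) {
    hits_fasta <- file.path(config$output_dir, "hits.fasta")
    write_fasta(hit_genes, hits_fasta)
  }

  abundance_path <- NULL
  if (!is.null(config$reads) && nrow(hit_genes) > 0L) {
    aln <- if (is.character(config$reads)) {
      read_alignments(config$reads)
    } else {
      config$reads
    }
    lens <- ifelse(!is.na(hit_genes$start) & !is.na(hit_genes$end),
                   hit_genes$end - hit_genes$start + 1L,
                   3L * (nchar(hit_genes$seq) + 1L))
    gene_lengths <- stats::setNames(as.integer(lens), hit_genes$id)
    counts <- count_reads(aln, gene_lengths)
    ab <- normalize_counts(counts, gene_lengths)
    abundance_path <- file.path(config$output_dir, "abundance.csv")
    write_abundance(ab, abundance_path)
  }

  list(summary = summary_df, hits = hit_genes,
       summary_path = summary_path, hits_fasta_path = hits_fasta,
       abundance_path = abundance_path,
       stage_counts = list(genes_called = n_called,
                           dropped_nonstandard = n_dropped,
                           hits_prefilter = n_prefilter,
                           hits_postfilter = n_postfilter))
}

#' Write the screening summary CSV
#'
#' Fixed column order; scores at 6 significant digits; deterministic row
#' order (sample, polymer, descending bit score, id).
#'
#' @param rows hit `data.frame` as assembled by [run_pipeline()].
#' @param path output path.
#' @return the ordered `data.frame`, invisibly written to `path`.
#' @export
write_summary <- function(rows, path) {
  cols <- c("protein_id", "sample", "polymer", "tool", "evalue",
            "bitscore", "bias", "ml_mode", "ml_score",
            "passes_high_confidence")
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  for (col in c("sample", "ml_mode")) {
    if (is.null(rows[[col]])) rows[[col]] <- ""
  }
  if (is.null(rows$ml_score)) rows$ml_score <- NA_real_
  if (is.null(rows$passes_high_confidence)) {
    rows$passes_high_confidence <- FALSE
  }
  ord <- order(rows$sample, rows$polymer, -rows$bitscore, rows$protein_id,
               method = "radix")
  out <- rows[ord, cols, drop = FALSE]
  for (col in c("evalue", "bitscore", "bias", "ml_score")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}
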