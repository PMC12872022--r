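#' Pairwise-alignment scoring parameters
#'
#' Karlin-Altschul constants default to the standard gapped-BLOSUM62
#' values used to convert raw Smith-Waterman scores to bits.
#'
#' @param matrix substitution matrix name (only `"BLOSUM62"` is shipped).
#' @param gap_open,gap_extend positive gap penalties; a gap of length g
#'   costs `gap_open + g * gap_extend`.
#' @param karlin_lambda,karlin_K positive Karlin-Altschul constants.
#' @return a list of class `pairwise_params`.
#' @export
pairwise_params <- function(matrix = "BLOSUM62", gap_open = 11,
                            gap_extend = 1, karlin_lambda = 0.267,
                            karlin_K = 0.041) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (karlin_lambda <= 0 || karlin_K <= 0) stop("lambda, K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_K = karlin_K),
            class = "pairwise_params")
}

.pkg_cache <- new.env(parent = emptyenv())

substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (is.null(.pkg_cache[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .pkg_cache[[key]] <- e[[name]]
  }
  .pkg_cache[[key]]
}

#' Global pairwise identity between two proteins
#'
#' Needleman-Wunsch global alignment under [pairwise_params()]; identity is
#' the number of identical aligned residues divided by the length of the
#' shorter sequence (CD-HIT convention).
#'
#' @param a,b non-empty protein strings.
#' @param params a [pairwise_params()] object.
#' @return a fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, params = pairwise_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Sequences are sorted by length descending (ties broken by id), then
#' scanned in order; each sequence joins the first existing representative
#' with identity >= `threshold`, otherwise it founds a new cluster.  The
#' representative is always the longest member.
#'
#' @param seqs protein sequence-record `data.frame` with unique ids.
#' @param threshold identity threshold in `(0, 1]` (default 0.95).
#' @param params a [pairwise_params()] object.
#' @return a `data.frame` with columns `representative_id`, `member_id`,
#'   `identity_to_rep`; the identity threshold is kept as the
#'   `"threshold"` attribute.
#' @export
greedy_cluster <- function(seqs, threshold = 0.95,
                           params = pairwise_params()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (anyDuplicated(seqs$id)) stop("duplicate ids in input")
  ord <- order(-nchar(seqs$seq), seqs$id, method = "radix")
  ids <- seqs$id[ord]; ss <- seqs$seq[ord]
  reps <- character(0); rep_seq <- character(0)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    assigned <- FALSE
    for (r in seq_along(reps)) {
      idn <- pairwise_identity(ss[i], rep_seq[r], params)
      if (idn >= threshold) {
        out[[i]] <- data.frame(representative_id = reps[r],
                               member_id = ids[i], identity_to_rep = idn,
                               stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, ids[i]); rep_seq <- c(rep_seq, ss[i])
      out[[i]] <- data.frame(representative_id = ids[i], member_id = ids[i],
                             identity_to_rep = 1.0, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "threshold") <- threshold
  res
}

#' Pairwise local-alignment search (fallback for singleton seed sets)
#'
#' Smith-Waterman local alignment of the query against every target.  Raw
#' scores are converted to bits `S = (lambda * S_raw - ln K) / ln 2` and
#' E-values `E = m * n * 2^-S` with `m` the query length and `n` the total
#' target length.  Bias is fixed at 0 for this tool.  The best hit per
#' target is reported, sorted by descending bit score (ties by target id).
#'
#' @param query a one-row protein record (or list with `id`, `seq`).
#' @param targets non-empty protein sequence-record `data.frame`.
#' @param polymer polymer label stamped on the hits.
#' @param params a [pairwise_params()] object.
#' @param db_size optional override for the total target length `n`.
#' @return a homology-hit `data.frame` (see [filter_hits()]).
#' @export
pairwise_search <- function(query, targets, polymer = NA_character_,
                            params = pairwise_params(), db_size = NULL) {
  qseq <- query$seq[[1]]; qid <- query$id[[1]]
  if (is.null(qseq) || !nzchar(qseq)) stop("empty query")
  if (is.null(targets) || nrow(targets) == 0L) stop("empty target set")
  n_total <- if (is.null(db_size)) sum(nchar(targets$seq)) else db_size
  m <- nchar(qseq)
  raw <- vapply(targets$seq, function(t) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(qseq), Biostrings::AAString(t), type = "local",
      substitutionMatrix = substitution_matrix(params$matrix),
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  bits <- (params$karlin_lambda * raw - log(params$karlin_K)) / log(2)
  ev <- m * n_total * 2^(-bits)
  out <- data.frame(protein_id = qid, polymer = polymer,
                    tool = "DIAMOND-like", bitscore = bits, evalue = ev,
                    bias = 0, ali_start = NA_integer_, ali_end = NA_integer_,
                    target_id = targets$id, stringsAsFactors = FALSE)
  out[order(-out$bitscore, out$target_id, method = "radix"), , drop = FALSE]
}

#' Apply the homology hit filters
#'
#' A hit is kept iff `evalue < evalue_max` AND `bitscore > bitscore_min`
#' AND, for HMM hits only, `bias < bias_fraction * bitscore`.  All
#' inequalities are strict; input order is preserved.
#'
#' @param hits homology-hit `data.frame` with columns `protein_id`,
#'   `polymer`, `tool`, `bitscore`, `evalue`, `bias`.
#' @param evalue_max E-value ceiling (default `1e-5`).
#' @param bitscore_min bit-score floor (default 20).
#' @param bias_fraction maximal bias as a fraction of the bit score for
#'   HMM hits (default 0.10).
#' @return the filtered subset, original order preserved.
#' @export
filter_hits <- function(hits, evalue_max = 1e-5, bitscore_min = 20,
                        bias_fraction = 0.10) {
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  keep <- hits$evalue < evalue_max & hits$bitscore > bitscore_min &
    (hits$tool != "HMMER-like" | hits$bias < bias_fraction * hits$bitscore)
  hits[keep, , drop = FALSE]
}
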