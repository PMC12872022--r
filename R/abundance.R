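#' Count reads per gene from alignment records
#'
#' Counts mapped, primary, non-supplementary alignments per reference
#' gene; each mate of a pair counts as one read.  Genes without
#' alignments get a count of 0.
#'
#' @param alignments alignment `data.frame` from [read_alignments()] (or
#'   generated).
#' @param gene_lengths named integer vector: gene id -> length in bp.
#'   Every alignment reference must be present.
#' @return named integer vector of raw counts, one entry per gene.
#' @export
count_reads <- function(alignments, gene_lengths) {
  genes <- names(gene_lengths)
  counts <- stats::setNames(integer(length(genes)), genes)
  if (!is.null(alignments) && nrow(alignments) > 0L) {
    use <- alignments$mapped & alignments$primary & !alignments$supplementary
    refs <- alignments$ref_id[use]
    unknown <- setdiff(unique(refs), genes)
    if (length(unknown)) {
      stop("alignment reference(s) not in gene set: ",
           paste(unknown, collapse = ", "))
    }
    tab <- table(refs)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Normalize gene counts to CPM, RPKM and TPM
#'
#' With `N` the total mapped reads over the quantified genes:
#' `CPM = c/N * 1e6`; `RPKM = c / (l/1000 * N/1e6)`;
#' `TPM = (c/l) / sum(c/l) * 1e6`.  When `N = 0` all normalized fields
#' are 0 and a warning is raised.
#'
#' @param counts named numeric vector of raw counts.
#' @param lengths named numeric vector of gene lengths in bp (positive),
#'   covering every counted gene.
#' @return a `data.frame` with columns `gene_id`, `length_bp`,
#'   `raw_count`, `cpm`, `rpkm`, `tpm`.
#' @export
normalize_counts <- function(counts, lengths) {
  genes <- names(counts)
  if (is.null(genes)) stop("counts must be named by gene id")
  if (!all(genes %in% names(lengths))) stop("missing gene length(s)")
  l <- as.numeric(lengths[genes])
  if (any(l < 1)) stop("gene lengths must be >= 1 bp")
  c_g <- as.numeric(counts)
  N <- sum(c_g)
  if (N == 0) {
    warning("no mapped reads: normalized abundances set to 0")
    cpm <- rpkm <- tpm <- rep(0, length(c_g))
  } else {
    cpm <- c_g / N * 1e6
    rpkm <- c_g / (l / 1000 * N / 1e6)
    rate <- c_g / l
    tpm <- rate / sum(rate) * 1e6
  }
  data.frame(gene_id = genes, length_bp = as.integer(l), raw_count = c_g,
             cpm = cpm, rpkm = rpkm, tpm = tpm, stringsAsFactors = FALSE)
}

#' Write an abundance table as CSV (6-decimal fixed formatting)
#'
#' @param abundance a `data.frame` from [normalize_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(abundance, path) {
  out <- abundance
  for (col in c("cpm", "rpkm", "tpm")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
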