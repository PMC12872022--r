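#' ORF-calling parameters
#'
#' @param min_aa_len minimum protein length in residues (stop excluded).
#' @param both_strands scan the reverse complement as well.
#' @return a list of class `orf_params`.
#' @export
orf_params <- function(min_aa_len = 30L, both_strands = TRUE) {
  min_aa_len <- as.integer(min_aa_len)
  if (is.na(min_aa_len) || min_aa_len < 1L) stop("min_aa_len must be >= 1")
  structure(list(min_aa_len = min_aa_len, both_strands = both_strands),
            class = "orf_params")
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Scan one strand/frame of a nucleotide string for maximal start-to-stop
# ORFs.  Codons containing N act as barriers: no ORF may span them.  For
# each stop, the earliest start codon since the previous barrier/stop wins
# (one gene per stop; nested shorter ORFs are suppressed).
scan_frame <- function(s, frame, min_aa_len) {
  n <- nchar(s)
  if (n - frame < 6L) return(NULL)
  cs <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(s, cs, cs + 2L)
  is_stop <- codons %in% STOP_CODONS
  has_n <- grepl("N", codons, fixed = TRUE)
  is_start <- codons %in% START_CODONS & !has_n
  orfs <- list()
  pending <- NA_integer_
  for (j in seq_along(codons)) {
    if (has_n[j]) {
      pending <- NA_integer_
    } else if (is_stop[j]) {
      if (!is.na(pending) && (j - pending) >= min_aa_len) {
        prot <- translate_codons(codons[pending:(j - 1L)])
        substr(prot, 1L, 1L) <- "M"  # alternative starts read as Met
        orfs[[length(orfs) + 1L]] <- list(
          nt_start = cs[pending], nt_end = cs[j] + 2L, protein = prot)
      }
      pending <- NA_integer_
    } else if (is_start[j] && is.na(pending)) {
      pending <- j
    }
  }
  orfs
}

#' Find open reading frames in a nucleotide sequence
#'
#' Reports all maximal start-to-stop ORFs (starts ATG/GTG/TTG, translated
#' with an initial Met) of at least `min_aa_len` residues on all six frames.
#' Reported coordinates are 1-based inclusive on the forward strand and
#' include the stop codon; the stop is excluded from the protein.
#'
#' @param contig a single-row nucleotide sequence record (see
#'   [seq_records()]), or a list with `id` and `seq`.
#' @param params an [orf_params()] object.
#' @return a protein sequence-record `data.frame` with provenance columns
#'   (`source_contig`, `start`, `end`, `strand`); ids are
#'   `"<contig>_<n>"`, numbered along the forward strand.
#' @export
find_orfs <- function(contig, params = orf_params()) {
  s <- toupper(contig$seq[[1]])
  id <- contig$id[[1]]
  if (grepl("[^ACGTN]", s)) {
    stop("non-nucleotide alphabet in contig ", id)
  }
  n <- nchar(s)
  found <- list()
  for (frame in 0:2) {
    for (o in scan_frame(s, frame, params$min_aa_len)) {
      found[[length(found) + 1L]] <- data.frame(
        protein = o$protein, start = o$nt_start, end = o$nt_end,
        strand = "+", stringsAsFactors = FALSE)
    }
  }
  if (isTRUE(params$both_strands)) {
    rc <- reverse_complement(s)
    for (frame in 0:2) {
      for (o in scan_frame(rc, frame, params$min_aa_len)) {
        found[[length(found) + 1L]] <- data.frame(
          protein = o$protein, start = n - o$nt_end + 1L,
          end = n - o$nt_start + 1L, strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(found) == 0L) {
    return(seq_records(character(), character())[0, ])
  }
  df <- do.call(rbind, found)
  ord <- order(df$start, df$end, df$strand, method = "radix")
  df <- df[ord, , drop = FALSE]
  seq_records(id = paste0(id, "_", seq_len(nrow(df))), seq = df$protein,
              alphabet = "protein",
              sample = if ("sample" %in% names(contig)) contig$sample[[1]] else NA,
              source_contig = id, start = df$start, end = df$end,
              strand = df$strand)
}

#' Call genes from contigs, genomes or proteins
#'
#' In `proteins` mode the input is passed through unchanged; otherwise
#' [find_orfs()] is applied to every input record.
#'
#' @param input a sequence-record `data.frame`.
#' @param mode `"contigs"`, `"genome"` or `"proteins"`.
#' @param params an [orf_params()] object.
#' @return a protein sequence-record `data.frame`.
#' @export
call_genes <- function(input, mode = c("contigs", "genome", "proteins"),
                       params = orf_params()) {
  mode <- match.arg(mode)
  if (nrow(input) == 0L) stop("no input records")
  looks_nt <- !grepl("[^ACGTN]", toupper(input$seq))
  if (mode == "proteins") {
    return(input)
  }
  if (any(!looks_nt)) {
    stop("non-nucleotide input in ", mode, " mode: ",
         paste(utils::head(input$id[!looks_nt], 3L), collapse = ", "))
  }
  out <- lapply(seq_len(nrow(input)), function(i) {
    find_orfs(input[i, , drop = FALSE], params)
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (length(out) == 0L) return(seq_records(character(), character())[0, ])
  do.call(rbind, out)
}
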