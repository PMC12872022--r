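#' Specification of a synthetic seed enzyme family
#'
#' @param polymer polymer label.
#' @param consensus_length consensus length in residues (>= 30).
#' @param n_members number of family members.
#' @param identity_band numeric pair `(lo, hi)` with `0 < lo <= hi <= 1`:
#'   realized member identity to the consensus must fall in this band.
#' @param indel_rate per-position probability of an indel event in a
#'   member (default 0: substitutions only, exact alignment by
#'   construction).
#' @param seed RNG seed.
#' @return a list of class `family_spec`.
#' @export
family_spec <- function(polymer, consensus_length = 120L, n_members = 10L,
                        identity_band = c(0.7, 0.9), indel_rate = 0,
                        seed = 42L) {
  if (consensus_length < 30L) stop("consensus_length must be >= 30")
  lo <- identity_band[1]; hi <- identity_band[2]
  if (!(lo > 0 && lo <= hi && hi <= 1)) {
    stop("identity_band must satisfy 0 < lo <= hi <= 1")
  }
  structure(list(polymer = polymer,
                 consensus_length = as.integer(consensus_length),
                 n_members = as.integer(n_members),
                 identity_band = c(lo, hi), indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# skewed residue frequencies, seeded; leading Met fixed so back-translated
# genes begin with a genuine start codon
draw_family_freqs <- function() {
  p <- rexp(20) + 0.2
  stats::setNames(p / sum(p), AA)
}

mutate_member <- function(consensus_chars, target_identity, freqs,
                          indel_rate) {
  len <- length(consensus_chars)
  n_sub <- round((1 - target_identity) * len)
  chars <- consensus_chars
  gaps <- rep(FALSE, len)       # deletions (gap in the member row)
  ins_after <- vector("list", len)
  if (n_sub > 0) {
    pos <- sample(2:len, n_sub)
    for (j in pos) {
      alt <- setdiff(AA, chars[j])
      w <- freqs[alt]
      chars[j] <- sample(alt, 1L, prob = w / sum(w))
    }
  }
  if (indel_rate > 0) {
    n_events <- rbinom(1L, len, indel_rate)
    if (n_events > 0) {
      at <- sample(2:(len - 1L), min(n_events, len - 2L))
      for (j in at) {
        if (runif(1) < 0.5) {
          gaps[j] <- TRUE
        } else {
          ins_after[[j]] <- sample(AA, 1L, prob = freqs)
        }
      }
    }
  }
  list(chars = chars, gaps = gaps, ins_after = ins_after)
}

#' Generate a synthetic seed enzyme family with a known alignment
#'
#' Draws a consensus from a family-specific skewed residue distribution
#' (leading Met fixed), derives members by seeded substitutions and
#' optional indels, and verifies with [pairwise_identity()] that every
#' realized identity to the consensus falls inside the requested band
#' (members are redrawn up to 60 times, then an error is raised).  The
#' multiple sequence alignment is produced by construction, so no aligner
#' is needed.
#'
#' @param spec a [family_spec()].
#' @return a list with `polymer`, `consensus`, `members` (sequence
#'   records, ids `"<polymer>_m<i>"`), `msa` (aligned rows, gap `-`),
#'   `freqs` and `spec`.
#' @export
generate_family <- function(spec) {
  set.seed(spec$seed)
  freqs <- draw_family_freqs()
  len <- spec$consensus_length
  consensus_chars <- c("M", sample(AA, len - 1L, replace = TRUE,
                                   prob = freqs))
  consensus <- paste(consensus_chars, collapse = "")
  lo <- spec$identity_band[1]; hi <- spec$identity_band[2]
  members <- vector("list", spec$n_members)
  for (i in seq_len(spec$n_members)) {
    ok <- FALSE
    for (try in seq_len(60L)) {
      u <- runif(1, lo, hi)
      mm <- mutate_member(consensus_chars, u, freqs, spec$indel_rate)
      seq_chars <- character(0)
      for (j in seq_len(len)) {
        if (!mm$gaps[j]) seq_chars <- c(seq_chars, mm$chars[j])
        if (!is.null(mm$ins_after[[j]])) {
          seq_chars <- c(seq_chars, mm$ins_after[[j]])
        }
      }
      s <- paste(seq_chars, collapse = "")
      idn <- pairwise_identity(s, consensus)
      if (idn >= lo && idn <= hi) {
        members[[i]] <- mm
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("identity band (", lo, ", ", hi, ") infeasible after 60 tries")
    }
  }
  # assemble the by-construction MSA: consensus columns plus the union of
  # member-specific insertions after each column
  max_ins <- vapply(seq_len(len), function(j) {
    max(c(0L, vapply(members, function(m) length(m$ins_after[[j]]), 1L)))
  }, 1L)
  rows <- vapply(members, function(m) {
    out <- character(0)
    for (j in seq_len(len)) {
      out <- c(out, if (m$gaps[j]) "-" else m$chars[j])
      ins <- m$ins_after[[j]]
      ni <- length(ins)
      if (max_ins[j] > 0L) {
        out <- c(out, c(ins, rep("-", max_ins[j] - ni)))
      }
    }
    paste(out, collapse = "")
  }, character(1))
  member_seqs <- gsub("-", "", rows, fixed = TRUE)
  recs <- seq_records(id = paste0(spec$polymer, "_m", seq_along(rows)),
                      seq = member_seqs, alphabet = "protein")
  list(polymer = spec$polymer, consensus = consensus, members = recs,
       msa = rows, freqs = freqs, spec = spec)
}

codon_table_by_aa <- function() {
  if (is.null(.pkg_cache$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    .pkg_cache$codons_by_aa <- split(names(gc), unname(gc))
  }
  .pkg_cache$codons_by_aa
}

# uniform synonymous-codon back-translation; appends a stop codon
back_translate <- function(protein) {
  tab <- codon_table_by_aa()
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
  paste(c(codons, sample(STOP_CODONS, 1L)), collapse = "")
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic metagenome with planted genes and known truth
#'
#' Every family member (and `n_background_genes` non-homologous decoy
#' proteins drawn from the pooled, shuffled family residues) is
#' back-translated with uniform synonymous codons, wrapped with its start
#' and a stop codon, and embedded at recorded coordinates and strands in
#' random background DNA.  An in-frame stop codon is placed immediately
#' upstream of each gene so the ORF caller recovers exactly the planted
#' protein.
#'
#' @param families list of [generate_family()] results (>= 1).
#' @param n_background_genes number of decoy genes to plant.
#' @param contig_length_range approximate contig length range in bp
#'   (spacer lengths are drawn to fit; a contig too short for its genes
#'   is an error).
#' @param depth_default read-pair depth recorded for every gene.
#' @param seed RNG seed.
#' @return a list with `contigs` (nucleotide records) and `truth`
#'   (`data.frame`: `gene_id`, `polymer` (`"negative"` for decoys),
#'   `contig`, `start`, `end`, `strand`, `depth`, `protein`, `gene_nt`).
#' @export
generate_metagenome <- function(families, n_background_genes = 5L,
                                contig_length_range = c(3000L, 6000L),
                                depth_default = 10L, seed = 42L) {
  if (length(families) == 0L) stop("at least one family is required")
  set.seed(seed)
  genes <- list()
  for (fam in families) {
    for (i in seq_len(nrow(fam$members))) {
      genes[[length(genes) + 1L]] <- list(
        gene_id = fam$members$id[i], polymer = fam$polymer,
        protein = fam$members$seq[i])
    }
  }
  pool <- unlist(strsplit(paste(vapply(families, function(f)
    paste(f$members$seq, collapse = ""), character(1)), collapse = ""), ""))
  mean_len <- round(mean(nchar(vapply(families, function(f)
    f$consensus, character(1)))))
  for (b in seq_len(n_background_genes)) {
    prot <- paste(c("M", sample(pool, mean_len - 1L)), collapse = "")
    genes[[length(genes) + 1L]] <- list(
      gene_id = paste0("bg_", b), polymer = "negative", protein = prot)
  }
  genes <- genes[sample(length(genes))]
  n_contigs <- max(1L, ceiling(length(genes) / 3L))
  assignment <- rep(seq_len(n_contigs), length.out = length(genes))
  contigs <- list(); truth <- list()
  for (ci in seq_len(n_contigs)) {
    gs <- genes[assignment == ci]
    target_len <- sample(seq(contig_length_range[1], contig_length_range[2]),
                         1L)
    gene_nts <- lapply(gs, function(g) back_translate(g$protein))
    need <- sum(vapply(gene_nts, nchar, 1L)) + 3L * length(gs)
    if (need > target_len) {
      stop("contig of length ", target_len, " too short for its ",
           length(gs), " gene(s)")
    }
    spare <- target_len - need
    cuts <- sort(sample.int(spare + 1L, length(gs), replace = TRUE) - 1L)
    spacers <- diff(c(0L, cuts))
    parts <- character(0); cursor <- 0L
    for (gi in seq_along(gs)) {
      sp <- random_dna(spacers[gi])
      parts <- c(parts, sp); cursor <- cursor + nchar(sp)
      strand <- sample(c("+", "-"), 1L)
      gn <- gene_nts[[gi]]
      segment <- paste0("TAA", gn)  # in-frame guard stop
      if (strand == "-") {
        segment <- reverse_complement(segment)
        gstart <- cursor + 1L
        gend <- cursor + nchar(gn)
      } else {
        gstart <- cursor + 4L
        gend <- cursor + 3L + nchar(gn)
      }
      parts <- c(parts, segment); cursor <- cursor + nchar(segment)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gs[[gi]]$gene_id, polymer = gs[[gi]]$polymer,
        contig = paste0("contig_", ci), start = gstart, end = gend,
        strand = strand, depth = depth_default,
        protein = gs[[gi]]$protein, gene_nt = gn,
        stringsAsFactors = FALSE)
    }
    tail_len <- target_len - cursor
    parts <- c(parts, random_dna(tail_len))
    contigs[[ci]] <- paste(parts, collapse = "")
  }
  contig_recs <- seq_records(id = paste0("contig_", seq_len(n_contigs)),
                             seq = unlist(contigs),
                             alphabet = "nucleotide")
  list(contigs = contig_recs, truth = do.call(rbind, truth))
}

#' Generate deterministic paired reads and true alignments for a truth set
#'
#' For each gene with depth > 0, `depth` read pairs are tiled evenly
#' across the gene sequence (error-free, deterministic: no sampling), and
#' a matching SAM of true alignments against the gene sequences is
#' emitted, so abundance tests need no aligner.  Each mate counts as one
#' read, so the expected raw count per gene is `2 * depth`.
#'
#' @param truth truth `data.frame` from [generate_metagenome()] (columns
#'   `gene_id`, `gene_nt`, `depth`).
#' @param read_length read length in bp (must not exceed any covered
#'   gene's length).
#' @param insert_size outer fragment length (clipped to the gene length).
#' @param out_dir output directory (created if needed).
#' @return a list with paths `fastq1`, `fastq2`, `sam` and
#'   `expected_counts` (named vector, `2 * depth` per covered gene).
#' @export
generate_reads <- function(truth, read_length = 100L, insert_size = 300L,
                           out_dir = tempfile("reads")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  covered <- truth[truth$depth > 0, , drop = FALSE]
  gl <- nchar(covered$gene_nt)
  if (any(read_length > gl)) {
    stop("read_length ", read_length, " exceeds a covered gene's length")
  }
  sq <- character(0); rows <- character(0)
  fq1 <- character(0); fq2 <- character(0)
  expected <- stats::setNames(2L * covered$depth, covered$gene_id)
  qual <- strrep("I", read_length)
  for (i in seq_len(nrow(covered))) {
    g <- covered[i, ]
    len <- nchar(g$gene_nt)
    ins <- max(read_length, min(insert_size, len))
    d <- g$depth
    starts <- if (d == 1L) 1L else {
      1L + floor((seq_len(d) - 1L) * (len - ins) / (d - 1L))
    }
    sq <- c(sq, paste0("@SQ\tSN:", g$gene_id, "\tLN:", len))
    for (j in seq_len(d)) {
      s1 <- starts[j]
      s2 <- s1 + ins - read_length
      r1 <- substr(g$gene_nt, s1, s1 + read_length - 1L)
      r2 <- reverse_complement(substr(g$gene_nt, s2, s2 + read_length - 1L))
      qn <- paste0(g$gene_id, "_p", j)
      rows <- c(rows,
        paste(qn, 99L, g$gene_id, s1, 60L, paste0(read_length, "M"), "=",
              s2, ins, r1, qual, sep = "\t"),
        paste(qn, 147L, g$gene_id, s2, 60L, paste0(read_length, "M"), "=",
              s1, -ins, reverse_complement(r2), qual, sep = "\t"))
      fq1 <- c(fq1, paste0("@", qn, "/1"), r1, "+", qual)
      fq2 <- c(fq2, paste0("@", qn, "/2"), r2, "+", qual)
    }
  }
  sam_path <- file.path(out_dir, "truth.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", sq, rows), sam_path)
  fq1_path <- file.path(out_dir, "reads_1.fastq")
  fq2_path <- file.path(out_dir, "reads_2.fastq")
  writeLines(fq1, fq1_path)
  writeLines(fq2, fq2_path)
  list(fastq1 = fq1_path, fastq2 = fq2_path, sam = sam_path,
       expected_counts = expected)
}
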