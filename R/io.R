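#' Construct a collection of sequence records
#'
#' A sequence record collection is a plain `data.frame` with one row per
#' sequence and columns `id`, `seq`, `description`, `alphabet`, `sample`,
#' `source_contig`, `start`, `end`, `strand`.  Coordinates are 1-based,
#' inclusive, on the forward strand of the source contig and include the
#' stop codon for called genes.
#'
#' @param id character vector of unique, non-empty ids.
#' @param seq character vector of residue strings (uppercased).
#' @param alphabet `"protein"` or `"nucleotide"` (recycled).
#' @param sample,source_contig,description optional character metadata.
#' @param start,end optional 1-based inclusive coordinates.
#' @param strand optional `"+"`/`"-"`.
#' @return a `data.frame` of sequence records.
#' @export
seq_records <- function(id, seq, alphabet = "protein", sample = NA_character_,
                        source_contig = NA_character_, start = NA_integer_,
                        end = NA_integer_, strand = NA_character_,
                        description = id) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq lengths differ")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(seq))) {
    stop("empty sequence for id(s): ", paste(id[!nzchar(seq)], collapse = ", "))
  }
  df <- data.frame(id = id, seq = seq, description = as.character(description),
                   alphabet = rep_len(alphabet, length(id)),
                   sample = rep_len(as.character(sample), length(id)),
                   source_contig = rep_len(as.character(source_contig), length(id)),
                   start = rep_len(as.integer(start), length(id)),
                   end = rep_len(as.integer(end), length(id)),
                   strand = rep_len(as.character(strand), length(id)),
                   stringsAsFactors = FALSE)
  has_coord <- !is.na(df$start) & !is.na(df$end)
  if (any(has_coord & (df$start < 1L | df$end < df$start))) {
    stop("invalid coordinates: need 1 <= start <= end")
  }
  df
}

#' Read a FASTA file
#'
#' The id is the first whitespace-delimited header token; the full header is
#' kept as `description`.  Residues are uppercased.  Duplicate ids and empty
#' files are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"` tag for the records.
#' @param sample optional sample label attached to every record.
#' @return a sequence-record `data.frame` (see [seq_records()]).
#' @export
read_fasta <- function(path, alphabet = "protein", sample = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("no records in FASTA file: ", path))
  if (length(x) == 0L) stop("no records in FASTA file: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  seq_records(id = ids, seq = as.character(x), alphabet = alphabet,
              sample = sample, description = headers)
}

#' Write records to FASTA (60-column wrapped)
#'
#' Headers are the record ids; input ordering is preserved.
#'
#' @param records sequence-record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot write an empty record collection")
  }
  x <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (fixture input)
#'
#' @param path path to a FASTQ file.
#' @param sample optional sample label.
#' @return a nucleotide sequence-record `data.frame`.
#' @export
read_fastq <- function(path, sample = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(x) == 0L) stop("no records in FASTQ file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  seq_records(id = ids, seq = as.character(x), alphabet = "nucleotide",
              sample = sample, description = names(x))
}

#' Read alignment records from SAM or BAM
#'
#' Returns one row per alignment with decoded flags; header reference
#' lengths are kept in the `"ref_lengths"` attribute (needed for RPKM).
#' Unmapped records carry `NA` positions.
#'
#' @param path path to a SAM or BAM file.
#' @param format `"auto"` (by extension), `"sam"` or `"bam"`.
#' @return a `data.frame` with columns `read_id`, `ref_id`, `pos`, `mapq`,
#'   `mapped`, `primary`, `supplementary`, `mate`.
#' @export
read_alignments <- function(path, format = c("auto", "sam", "bam")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "sam"
  }
  bam <- path
  if (format == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            indexDestination = FALSE, overwrite = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  ref_lengths <- hdr$targets
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  mapped <- bitwAnd(flag, 0x4L) == 0L
  rid <- as.character(b$rname)
  if (any(mapped & is.na(rid))) {
    stop("mapped alignment with reference absent from header")
  }
  out <- data.frame(
    read_id = b$qname,
    ref_id = rid,
    pos = ifelse(mapped, b$pos, NA_integer_),
    mapq = b$mapq,
    mapped = mapped,
    primary = bitwAnd(flag, 0x100L) == 0L,
    supplementary = bitwAnd(flag, 0x800L) != 0L,
    mate = ifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L),
    stringsAsFactors = FALSE)
  attr(out, "ref_lengths") <- ref_lengths
  out
}
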