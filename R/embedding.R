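#' Preprocess a protein sequence for embedding
#'
#' Uppercases, trims leading/trailing runs of the ambiguity code `X` and
#' rejects sequences with any remaining nonstandard residue
#' (B, Z, J, U, O, `*`, internal X, ...), naming the offending position.
#'
#' @param seq non-empty protein string.
#' @return the cleaned sequence (standard 20-letter alphabet only).
#' @export
preprocess_sequence <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) stop("empty sequence")
  s <- toupper(seq)
  s <- sub("^X+", "", s)
  s <- sub("X+$", "", s)
  if (!nzchar(s)) stop("sequence empty after trimming ambiguous residues")
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% AA))
  if (length(bad)) {
    stop("nonstandard residue '", chars[bad[1]], "' at position ", bad[1])
  }
  s
}

# per-residue feature table for the default embedder -----------------------

# Kyte-Doolittle hydropathy
.KD <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
         I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
         R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
# net side-chain charge at pH 7 (His treated as neutral)
.CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0,
             K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
             T = 0, V = 0, W = 0, Y = 0)
.AROMATIC <- c(F = 1, W = 1, Y = 1)
.POLAR <- c(C = 1, D = 1, E = 1, H = 1, K = 1, N = 1, Q = 1, R = 1,
            S = 1, T = 1, Y = 1)
# monoisotopic residue masses (Da)
.MONO_MASS <- c(A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
                F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
                K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
                P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
                T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333)

default_feature_table <- function() {
  if (is.null(.pkg_cache$feat25)) {
    onehot <- diag(20)
    rownames(onehot) <- AA
    arom <- ifelse(AA %in% names(.AROMATIC), 1, 0)
    polar <- ifelse(AA %in% names(.POLAR), 1, 0)
    tab <- cbind(onehot,
                 hydropathy = .KD[AA] / 5,
                 charge = .CHARGE[AA],
                 aromatic = arom,
                 polar = polar,
                 mass = .MONO_MASS[AA] / 200)
    colnames(tab)[1:20] <- paste0("aa_", AA)
    .pkg_cache$feat25 <- tab
  }
  .pkg_cache$feat25
}

#' The default deterministic protein embedder
#'
#' A context-free per-residue embedder of dimension 25: a one-hot block
#' over the 20 standard residues (alphabetical order) concatenated with
#' five scaled physicochemical scalars (Kyte-Doolittle hydropathy / 5, net
#' charge at pH 7, aromaticity flag, polarity flag, monoisotopic mass /
#' 200).  Mean pooling of a context-free embedder is invariant to residue
#' order; only composition is encoded.
#'
#' @return an embedder contract: a list with `name`, `dim` and
#'   `per_residue(seq)` returning a length x dim matrix.
#' @export
default_embedder <- function() {
  tab <- default_feature_table()
  list(name = "onehot-physchem-v1", dim = 25L,
       per_residue = function(seq) {
         x <- encode_protein(seq)
         tab[x, , drop = FALSE]
       })
}

#' Embed a protein by mean pooling per-residue vectors
#'
#' @param seq preprocessed protein string (see [preprocess_sequence()]).
#' @param embedder an embedder contract (e.g. [default_embedder()]).
#' @param protein_id optional id recorded with the vector.
#' @return a list with `protein_id`, `values` (length-`dim` numeric) and
#'   `embedder_name`.
#' @export
embed_protein <- function(seq, embedder = default_embedder(),
                          protein_id = NA_character_) {
  m <- tryCatch(embedder$per_residue(seq), error = function(e) {
    stop("embedder '", embedder$name, "' failed for protein ",
         protein_id, ": ", conditionMessage(e))
  })
  if (nrow(m) != nchar(seq)) {
    stop("embedder contract violation for protein ", protein_id,
         ": ", nrow(m), " rows for ", nchar(seq), " residues")
  }
  list(protein_id = protein_id, values = colMeans(m),
       embedder_name = embedder$name)
}

#' Embed a collection of proteins into a matrix
#'
#' @param records protein sequence-record `data.frame` (already
#'   preprocessed).
#' @param embedder an embedder contract.
#' @return an n x dim numeric matrix with record ids as row names; the
#'   embedder name is kept as the `"embedder_name"` attribute.
#' @export
embed_records <- function(records, embedder = default_embedder()) {
  m <- t(vapply(seq_len(nrow(records)), function(i) {
    embed_protein(records$seq[i], embedder, records$id[i])$values
  }, numeric(embedder$dim)))
  rownames(m) <- records$id
  attr(m, "embedder_name") <- embedder$name
  m
}

#' Adapter for an external protein language model
#'
#' Wraps an external per-residue model behind the embedder contract used
#' by [embed_protein()].  The model source must be a list with a `dim`
#' field and an `encode(text)` function accepting a space-separated
#' residue string and returning a matrix of per-token vectors; special
#' token rows (one leading, one trailing) are stripped before pooling when
#' present.  No external model is required by any other part of the
#' package: the pipeline runs with [default_embedder()].
#'
#' @param model_source the model wrapper described above, or `NULL`.
#' @param name embedder name recorded with the vectors.
#' @return an embedder contract.
#' @export
protbert_adapter <- function(model_source, name = "protbert") {
  if (is.null(model_source) || !is.list(model_source) ||
      !is.function(model_source$encode) || is.null(model_source$dim)) {
    stop("external protein language model unavailable; ",
         "use default_embedder() instead")
  }
  dim <- as.integer(model_source$dim)
  list(name = name, dim = dim,
       per_residue = function(seq) {
         spaced <- paste(strsplit(seq, "")[[1]], collapse = " ")
         m <- model_source$encode(spaced)
         n <- nchar(seq)
         if (nrow(m) == n + 2L) m <- m[2:(n + 1L), , drop = FALSE]
         if (nrow(m) != n) {
           stop("model returned ", nrow(m), " token rows for ", n,
                " residues")
         }
         if (ncol(m) != dim) stop("model hidden dimension mismatch")
         m
       })
}
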