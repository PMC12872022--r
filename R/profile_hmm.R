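#' Build a per-polymer profile HMM from a seed multiple sequence alignment
#'
#' Alignment columns with a gap fraction below 0.5 become match states.
#' Match and insert emissions are observed counts plus
#' `pseudocount_weight` times the null background, normalized.  Node
#' transitions are estimated from each sequence's implied state path with
#' the same pseudocount scheme.  The null background is the amino-acid
#' frequency of the seed set (uniform 1/20 when the seed set holds fewer
#' than 100 residues).
#'
#' @param msa aligned protein sequences of equal length: a character vector,
#'   or a sequence-record `data.frame` whose `seq` column holds the aligned
#'   rows (gap symbol `-`).
#' @param polymer polymer label (e.g. `"PET"`).
#' @param pseudocount_weight positive smoothing weight (default 1).
#' @return an object of class `profile_hmm`.
#' @export
build_profile <- function(msa, polymer, pseudocount_weight = 1.0) {
  if (is.data.frame(msa)) msa <- msa$seq
  msa <- toupper(as.character(msa))
  if (length(msa) < 2L) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(msa))) != 1L) stop("ragged alignment")
  if (pseudocount_weight <= 0) stop("pseudocount_weight must be positive")
  m <- do.call(rbind, strsplit(msa, ""))
  bad <- setdiff(unique(as.vector(m)), c(AA, "-", "."))
  if (length(bad)) stop("nonstandard alignment symbol(s): ",
                        paste(bad, collapse = ", "))
  m[m == "."] <- "-"
  nseq <- nrow(m); ncol_aln <- ncol(m)

  gap_frac <- colMeans(m == "-")
  match_cols <- which(gap_frac < 0.5)
  L <- length(match_cols)
  if (L == 0L) stop("alignment has zero match columns")

  residues <- as.vector(m[m != "-"])
  if (length(residues) >= 100L) {
    bg <- table(factor(residues, levels = AA))
    null_background <- as.numeric(bg) / sum(bg)
  } else {
    null_background <- rep(1 / 20, 20L)
  }
  names(null_background) <- AA
  w <- pseudocount_weight

  count_row <- function(chars) {
    as.numeric(table(factor(chars[chars != "-"], levels = AA)))
  }
  me <- t(vapply(match_cols, function(j) {
    cnt <- count_row(m[, j]) + w * null_background
    cnt / sum(cnt)
  }, numeric(20L)))
  colnames(me) <- AA

  # insert columns between match columns are assigned to the preceding node
  node_of_col <- rep(NA_integer_, ncol_aln)
  node_of_col[match_cols] <- seq_len(L)
  ins_node <- integer(ncol_aln)  # 0 = before first match (dropped)
  cur <- 0L
  for (j in seq_len(ncol_aln)) {
    if (!is.na(node_of_col[j])) cur <- node_of_col[j]
    else ins_node[j] <- cur
  }
  ie <- matrix(0, L, 20L, dimnames = list(NULL, AA))
  for (k in seq_len(L)) {
    cols <- which(ins_node == k & is.na(node_of_col))
    cnt <- if (length(cols)) count_row(as.vector(m[, cols, drop = FALSE])) else numeric(20L)
    cnt <- cnt + w * null_background
    ie[k, ] <- cnt / sum(cnt)
  }

  # transition counts from per-sequence state paths
  tc <- matrix(0, L, 7L,
               dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (i in seq_len(nseq)) {
    prev_state <- NULL; prev_node <- NULL
    for (j in seq_len(ncol_aln)) {
      k <- node_of_col[j]
      if (!is.na(k)) {
        st <- if (m[i, j] == "-") "D" else "M"
        nd <- k
      } else {
        if (m[i, j] == "-") next
        st <- "I"; nd <- ins_node[j]
        if (nd == 0L) next  # flanking insert before first match: skip
      }
      if (!is.null(prev_state)) {
        key <- paste0(prev_state, st)
        from <- prev_node
        if (key %in% colnames(tc) && from >= 1L && from <= L) {
          tc[from, key] <- tc[from, key] + 1
        }
      }
      prev_state <- st; prev_node <- nd
    }
  }
  trans <- matrix(0, L, 7L, dimnames = dimnames(tc))
  groups <- list(c("MM","MI","MD"), c("IM","II"), c("DM","DD"))
  for (k in seq_len(L)) {
    for (g in groups) {
      cnt <- tc[k, g] + w / length(g)
      trans[k, g] <- cnt / sum(cnt)
    }
  }
  # node L has no onward transitions; fixed degenerate rows (unused by DP)
  trans[L, ] <- c(1, 0, 0, 1, 0, 1, 0)

  structure(list(polymer = polymer, L = L,
                 match_emissions = me, insert_emissions = ie,
                 transitions = trans, null_background = null_background,
                 pseudocount_weight = w, calibration = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm: polymer=", x$polymer, ", L=", x$L,
      if (!is.null(x$calibration)) ", calibrated" else ", uncalibrated",
      "\n", sep = "")
  invisible(x)
}

encode_protein <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  x <- match(chars, AA)
  if (anyNA(x)) {
    pos <- which(is.na(x))[1]
    stop("nonstandard residue '", chars[pos], "' at position ", pos)
  }
  x
}

log_odds_matrices <- function(profile, null) {
  lnull <- matrix(log2(null), profile$L, 20L, byrow = TRUE)
  list(lm = log2(profile$match_emissions) - lnull,
       li = log2(profile$insert_emissions) - lnull,
       lt = log2(profile$transitions))
}

#' Forward bit score of a protein against a profile
#'
#' Sum over all alignment paths of the log2 odds of the profile versus the
#' null model, computed by dynamic programming in log space.  In `local`
#' mode the alignment may enter and exit at any match state (uniform
#' weights 1/L each); in `global` mode the whole sequence aligns from the
#' first to the last match state.
#'
#' @param profile a `profile_hmm`.
#' @param seq protein string over the 20 standard residues.
#' @param mode `"local"` (default) or `"global"`.
#' @param null optional replacement null background (20 probabilities);
#'   used by [bias_score()].
#' @return the score in bits.
#' @export
forward_bitscore <- function(profile, seq, mode = c("local", "global"),
                             null = NULL) {
  mode <- match.arg(mode)
  if (is.null(null)) null <- profile$null_background
  x <- encode_protein(seq)
  lo <- log_odds_matrices(profile, null)
  phmm_forward(lo$lm, lo$li, lo$lt, x, mode == "local")
}

#' Viterbi alignment of a protein against a profile
#'
#' @inheritParams forward_bitscore
#' @return a list with `bits` (Viterbi score), `envelope` (first and last
#'   aligned residue, 1-based inclusive) and `path` (state labels).
#' @export
viterbi_align <- function(profile, seq, mode = c("local", "global"),
                          null = NULL) {
  mode <- match.arg(mode)
  if (is.null(null)) null <- profile$null_background
  x <- encode_protein(seq)
  lo <- log_odds_matrices(profile, null)
  v <- phmm_viterbi(lo$lm, lo$li, lo$lt, x, mode == "local")
  list(bits = v$bits, envelope = c(v$ali_start, v$ali_end), path = v$path)
}

# Maximum-likelihood Gumbel fit; location mu (bits), scale lam = 1/beta.
fit_gumbel <- function(x) {
  if (length(x) < 2L || stats::sd(x) == 0) {
    stop("degenerate score variance: cannot fit Gumbel")
  }
  s <- stats::sd(x); c0 <- mean(x)
  f <- function(beta) {
    w <- exp(-(x - c0) / beta)
    beta - mean(x) + sum(x * w) / sum(w)
  }
  lo <- s / 100; hi <- s * 100
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  mu <- c0 - beta * log(mean(exp(-(x - c0) / beta)))
  list(mu = mu, lam = 1 / beta)
}

#' Calibrate E-value parameters for a profile
#'
#' Scores `n_random` i.i.d. sequences drawn from the profile's null
#' background and fits a Gumbel distribution (location `mu`, scale `lam`)
#' to the forward bit scores by maximum likelihood.
#'
#' @param profile a `profile_hmm`.
#' @param n_random number of null sequences (>= 100).
#' @param len_distribution integer vector of sequence lengths to sample
#'   from (a scalar gives fixed length).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return an object of class `calibration_params` with fields `mu`,
#'   `lam`, `n_calibration`, `seed`.
#' @export
calibrate_evalues <- function(profile, n_random = 200L,
                              len_distribution = 150L, seed = 42L) {
  n_random <- as.integer(n_random)
  if (n_random < 100L) stop("n_calibration must be >= 100")
  set.seed(seed)
  lens <- if (length(len_distribution) == 1L) {
    rep_len(as.integer(len_distribution), n_random)
  } else {
    sample(as.integer(len_distribution), n_random, replace = TRUE)
  }
  scores <- vapply(lens, function(len) {
    s <- paste(sample(AA, len, replace = TRUE,
                      prob = profile$null_background), collapse = "")
    forward_bitscore(profile, s)
  }, numeric(1))
  fit <- fit_gumbel(scores)
  structure(list(mu = fit$mu, lam = fit$lam, n_calibration = n_random,
                 seed = seed),
            class = "calibration_params")
}

#' Calibrate a profile in place
#'
#' Convenience wrapper returning the profile with its `calibration` field
#' set by [calibrate_evalues()].
#'
#' @inheritParams calibrate_evalues
#' @return the calibrated `profile_hmm`.
#' @export
calibrate_profile <- function(profile, n_random = 200L,
                              len_distribution = 150L, seed = 42L) {
  profile$calibration <- calibrate_evalues(profile, n_random,
                                           len_distribution, seed)
  profile
}

#' E-value of a bit score
#'
#' `P = 1 - exp(-exp(-lam * (S - mu)))` under the calibrated Gumbel null;
#' `E = db_size * P`.  Monotone non-increasing in `S`.
#'
#' @param S bit score(s).
#' @param cal a `calibration_params` object.
#' @param db_size number of sequences searched (>= 1).
#' @return expected number of equal-or-better false hits.
#' @export
evalue <- function(S, cal, db_size) {
  if (is.null(cal) || !inherits(cal, "calibration_params")) {
    stop("profile is not calibrated; run calibrate_evalues() first")
  }
  if (db_size < 1) stop("db_size must be >= 1")
  P <- -expm1(-exp(-cal$lam * (S - cal$mu)))
  db_size * P
}

#' Composition-bias score of a hit
#'
#' `B = max(0, S1 - S2)` where `S1` is the forward bit score under the
#' profile's null background and `S2` re-scores the sequence with the null
#' model replaced by the add-one-smoothed residue composition of the
#' alignment envelope.  Large `B` flags hits whose score is explained by
#' skewed composition rather than positional signal.
#'
#' @param profile a `profile_hmm`.
#' @param seq protein string.
#' @param envelope integer pair `(start, end)`, 1-based inclusive.
#' @return bias in bits (>= 0).
#' @export
bias_score <- function(profile, seq, envelope) {
  n <- nchar(seq)
  if (length(envelope) != 2L || envelope[1] < 1L || envelope[2] > n ||
      envelope[1] > envelope[2]) {
    stop("invalid or empty envelope")
  }
  sub <- substr(seq, envelope[1], envelope[2])
  cnt <- table(factor(strsplit(toupper(sub), "")[[1]], levels = AA))
  null2 <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
  names(null2) <- AA
  s1 <- forward_bitscore(profile, seq)
  s2 <- forward_bitscore(profile, seq, null = null2)
  max(0, s1 - s2)
}

#' Score a protein against a calibrated profile
#'
#' Runs the forward scorer, the Viterbi aligner (for the envelope), the
#' bias correction and the E-value in one call.
#'
#' @param profile a calibrated `profile_hmm`.
#' @param seq protein string.
#' @param protein_id id recorded in the hit.
#' @param db_size database size for the E-value.
#' @return a one-row homology-hit `data.frame` (see [filter_hits()]).
#' @export
score_protein <- function(profile, seq, protein_id, db_size) {
  S <- forward_bitscore(profile, seq)
  v <- viterbi_align(profile, seq)
  B <- bias_score(profile, seq, v$envelope)
  E <- evalue(S, profile$calibration, db_size)
  data.frame(protein_id = protein_id, polymer = profile$polymer,
             tool = "HMMER-like", bitscore = S, evalue = E, bias = B,
             ali_start = v$envelope[1], ali_end = v$envelope[2],
             target_id = NA_character_, stringsAsFactors = FALSE)
}

#' Serialize a profile to a plain-text file
#'
#' @param profile a `profile_hmm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  fmt <- function(x) paste(format(x, digits = 17, scientific = TRUE),
                           collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# plastizymr profile v1")
  wl("polymer\t", profile$polymer)
  wl("L\t", profile$L)
  wl("pseudocount_weight\t", format(profile$pseudocount_weight, digits = 17))
  wl("background\t", fmt(profile$null_background))
  wl("match_emissions")
  for (k in seq_len(profile$L)) wl(fmt(profile$match_emissions[k, ]))
  wl("insert_emissions")
  for (k in seq_len(profile$L)) wl(fmt(profile$insert_emissions[k, ]))
  wl("transitions")
  for (k in seq_len(profile$L)) wl(fmt(profile$transitions[k, ]))
  if (!is.null(profile$calibration)) {
    cal <- profile$calibration
    wl("calibration\t", format(cal$mu, digits = 17), "\t",
       format(cal$lam, digits = 17), "\t", cal$n_calibration, "\t", cal$seed)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path path to a profile text file.
#' @return a `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "# plastizymr profile v1") stop("not a plastizymr profile")
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, "\t"))][1]
    strsplit(ln, "\t")[[1]][-1]
  }
  L <- as.integer(kv("L"))
  numrow <- function(ln) as.numeric(strsplit(ln, "\t")[[1]])
  block <- function(name) {
    i <- which(lines == name)[1]
    t(vapply(lines[(i + 1):(i + L)], numrow, numeric(20L), USE.NAMES = FALSE))
  }
  me <- block("match_emissions"); colnames(me) <- AA
  ie <- block("insert_emissions"); colnames(ie) <- AA
  i <- which(lines == "transitions")[1]
  tr <- t(vapply(lines[(i + 1):(i + L)], numrow, numeric(7L),
                 USE.NAMES = FALSE))
  colnames(tr) <- c("MM","MI","MD","IM","II","DM","DD")
  bg <- as.numeric(kv("background")); names(bg) <- AA
  cal <- NULL
  cl <- lines[startsWith(lines, "calibration\t")]
  if (length(cl)) {
    v <- strsplit(cl[1], "\t")[[1]][-1]
    cal <- structure(list(mu = as.numeric(v[1]), lam = as.numeric(v[2]),
                          n_calibration = as.integer(v[3]),
                          seed = as.integer(v[4])),
                     class = "calibration_params")
  }
  structure(list(polymer = kv("polymer"), L = L, match_emissions = me,
                 insert_emissions = ie, transitions = tr,
                 null_background = bg,
                 pseudocount_weight = as.numeric(kv("pseudocount_weight")),
                 calibration = cal),
            class = "profile_hmm")
}
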