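# Independent oracles used to check the package implementation.
# These deliberately re-derive results by brute force / direct DP rather
# than calling the code paths they verify.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

lse2_r <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log2(2^(a - m) + 2^(b - m))
}

# Exhaustive enumeration of all alignment paths of a profile HMM against a
# sequence; sums (forward) or maximizes (viterbi) log2-odds path weights.
# Feasible only for tiny instances (L <= 4, |seq| <= 5).
phmm_enumerate <- function(profile, seq, mode = c("local", "global"),
                           null = profile$null_background,
                           viterbi = FALSE) {
  mode <- match.arg(mode)
  x <- match(strsplit(seq, "")[[1]], AA20)
  L <- profile$L
  n <- length(x)
  lnull <- matrix(log2(null), L, 20, byrow = TRUE)
  lm <- log2(profile$match_emissions) - lnull
  li <- log2(profile$insert_emissions) - lnull
  lt <- log2(profile$transitions)
  entry <- if (mode == "local") -log2(L) else 0
  exitw <- if (mode == "local") -log2(L) else 0
  agg <- if (viterbi) max else lse2_r
  total <- -Inf
  rec <- function(state, k, i, w) {
    if (state == "M") {
      if (mode == "local") total <<- agg(total, w + exitw)
      else if (k == L && i == n) total <<- agg(total, w)
      if (i < n) {
        if (k < L) rec("M", k + 1, i + 1, w + lt[k, "MM"] + lm[k + 1, x[i + 1]])
        if (k <= L - 1) rec("I", k, i + 1, w + lt[k, "MI"] + li[k, x[i + 1]])
      }
      if (k < L) rec("D", k + 1, i, w + lt[k, "MD"])
    } else if (state == "I") {
      if (i < n) {
        rec("I", k, i + 1, w + lt[k, "II"] + li[k, x[i + 1]])
        if (k < L) rec("M", k + 1, i + 1, w + lt[k, "IM"] + lm[k + 1, x[i + 1]])
      }
    } else { # D
      if (k < L) {
        if (i < n) rec("M", k + 1, i + 1, w + lt[k, "DM"] + lm[k + 1, x[i + 1]])
        rec("D", k + 1, i, w + lt[k, "DD"])
      }
    }
  }
  starts <- if (mode == "local") {
    expand.grid(i = seq_len(n), s = seq_len(L))
  } else {
    data.frame(i = 1L, s = 1L)
  }
  for (r in seq_len(nrow(starts))) {
    i0 <- starts$i[r]; s0 <- starts$s[r]
    rec("M", s0, i0, entry + lm[s0, x[i0]])
  }
  unname(total)
}

# random tiny ungapped/gapped MSA -> profile for oracle comparisons
random_tiny_profile <- function(L, nseq = 4L, gap_prob = 0.1) {
  repeat {
    rows <- replicate(nseq, {
      chars <- sample(AA20, L, replace = TRUE)
      gaps <- runif(L) < gap_prob
      chars[gaps] <- "-"
      paste(chars, collapse = "")
    })
    p <- tryCatch(build_profile(rows, "X", pseudocount_weight = 1.0),
                  error = function(e) NULL)
    if (!is.null(p) && p$L >= 2L) return(p)
  }
}

# independent affine Smith-Waterman; a gap of length g costs open + g * ext
sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  Fm <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      Fm[i, j] <- max(H[i - 1, j] - open - ext, Fm[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], Fm[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62_mat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# independent six-frame ORF scan used against find_orfs
orf_oracle <- function(seqstr, min_aa_len) {
  stops <- c("TAA", "TAG", "TGA"); starts <- c("ATG", "GTG", "TTG")
  scan1 <- function(s) {
    n <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      if (n - frame < 6) next
      cs <- seq(frame + 1, n - 2, by = 3)
      codons <- substring(s, cs, cs + 2)
      pending <- NA
      for (j in seq_along(codons)) {
        if (grepl("N", codons[j])) { pending <- NA; next }
        if (codons[j] %in% stops) {
          if (!is.na(pending) && (j - pending) >= min_aa_len) {
            aa <- unname(Biostrings::GENETIC_CODE[codons[pending:(j - 1)]])
            aa[1] <- "M"
            out[[length(out) + 1]] <- list(
              s = cs[pending], e = cs[j] + 2,
              prot = paste(aa, collapse = ""))
          }
          pending <- NA
        } else if (codons[j] %in% starts && is.na(pending)) pending <- j
      }
    }
    out
  }
  fw <- scan1(seqstr)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqstr)))
  n <- nchar(seqstr)
  rv <- lapply(scan1(rc), function(o) {
    list(s = n - o$e + 1, e = n - o$s + 1, prot = o$prot)
  })
  c(lapply(fw, function(o) c(o, strand = "+")),
    lapply(rv, function(o) c(o, strand = "-")))
}

# substitution-only mutant with a known identity to the source
mutate_identity <- function(seq, identity) {
  chars <- strsplit(seq, "")[[1]]
  n_sub <- round((1 - identity) * length(chars))
  if (n_sub > 0) {
    pos <- sample(2:length(chars), n_sub)
    for (j in pos) chars[j] <- sample(setdiff(AA20, chars[j]), 1)
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")
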