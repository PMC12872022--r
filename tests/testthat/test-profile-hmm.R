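test_that("build_profile handles degenerate and gapped alignments", {
  p <- build_profile(c("MKV", "MKV", "MKV"), "PET",
                     pseudocount_weight = 1e-9)
  expect_equal(p$L, 3L)
  expect_gt(p$match_emissions[1, "M"], 1 - 1e-6)
  expect_gt(p$match_emissions[2, "K"], 1 - 1e-6)
  expect_gt(p$match_emissions[3, "V"], 1 - 1e-6)
  # a column gapped in 2 of 3 sequences is not a match state
  p2 <- build_profile(c("M-KV", "MAKV", "M-KV"), "PET")
  expect_equal(p2$L, 3L)
  expect_error(build_profile(c("MK", "MKV"), "PET"), "ragged")
  expect_error(build_profile(c("--", "--", "--"), "PET"), "match columns")
})

test_that("emission rows match an independent count-and-normalize oracle", {
  set.seed(3)
  ncolumns <- 12; nseq <- 20
  rows <- replicate(nseq, random_protein(ncolumns))
  w <- 1.0
  p <- build_profile(rows, "PET", pseudocount_weight = w)
  expect_equal(p$L, ncolumns)
  m <- do.call(rbind, strsplit(rows, ""))
  residues <- as.vector(m)
  bg <- as.numeric(table(factor(residues, levels = AA20)))
  bg <- bg / sum(bg)
  for (j in seq_len(ncolumns)) {
    cnt <- as.numeric(table(factor(m[, j], levels = AA20)))
    want <- (cnt + w * bg) / (nseq + w)
    expect_equal(unname(p$match_emissions[j, ]), want, tolerance = 1e-12)
  }
  # structural invariants
  expect_equal(rowSums(p$match_emissions), rep(1, p$L), tolerance = 1e-9)
  expect_equal(rowSums(p$insert_emissions), rep(1, p$L), tolerance = 1e-9)
  tr <- p$transitions
  expect_equal(rowSums(tr[, c("MM", "MI", "MD")]), rep(1, p$L),
               tolerance = 1e-9)
  expect_equal(rowSums(tr[, c("IM", "II")]), rep(1, p$L), tolerance = 1e-9)
  expect_equal(rowSums(tr[, c("DM", "DD")]), rep(1, p$L), tolerance = 1e-9)
})

test_that("a zero-entropy profile scores its consensus in closed form", {
  p <- build_profile(c("MKV", "MKV", "MKV"), "PET",
                     pseudocount_weight = 1e-12)
  s <- forward_bitscore(p, "MKV", mode = "global")
  expect_equal(s, 3 * log2(20), tolerance = 1e-6)
  v <- viterbi_align(p, "MKV")
  expect_equal(v$envelope, c(1L, 3L))
  expect_equal(v$path, c("M1", "M2", "M3"))
})

test_that("forward and Viterbi equal exhaustive path enumeration", {
  set.seed(101)
  for (rep in 1:6) {
    p <- random_tiny_profile(L = sample(3:4, 1))
    for (len in c(2, 4, 5)) {
      s <- random_protein(len)
      for (mode in c("local", "global")) {
        fwd <- forward_bitscore(p, s, mode = mode)
        vit <- viterbi_align(p, s, mode = mode)$bits
        expect_equal(fwd, phmm_enumerate(p, s, mode), tolerance = 1e-9)
        expect_equal(vit, phmm_enumerate(p, s, mode, viterbi = TRUE),
                     tolerance = 1e-9)
        expect_gte(fwd, vit - 1e-9)
      }
    }
  }
})

test_that("nonstandard residues are rejected by the scorer", {
  p <- build_profile(c("MKV", "MKV"), "PET")
  expect_error(forward_bitscore(p, "MKB"), "position 3")
})

test_that("calibration is deterministic, shift-equivariant and recovers
           known Gumbel parameters", {
  prof <- pet_profile()
  c1 <- calibrate_evalues(prof, n_random = 150, len_distribution = 60:120,
                          seed = 7)
  c2 <- calibrate_evalues(prof, n_random = 150, len_distribution = 60:120,
                          seed = 7)
  expect_identical(c1, c2)
  expect_error(calibrate_evalues(prof, n_random = 50), ">= 100")
  # location equivariance of the fitter
  set.seed(13)
  x <- 5 - (1 / 0.7) * log(-log(runif(2000)))
  f1 <- plastizymr:::fit_gumbel(x)
  f2 <- plastizymr:::fit_gumbel(x + 3)
  expect_equal(f2$mu, f1$mu + 3, tolerance = 1e-6)
  expect_equal(f2$lam, f1$lam, tolerance = 1e-9)
  expect_error(plastizymr:::fit_gumbel(rep(1, 100)), "degenerate")
  # parameter recovery at n = 5000
  set.seed(13)
  x <- 5 - (1 / 0.7) * log(-log(runif(5000)))
  fit <- plastizymr:::fit_gumbel(x)
  expect_lt(abs(fit$mu - 5) / 5, 0.05)
  expect_lt(abs(fit$lam - 0.7) / 0.7, 0.05)
})

test_that("E-values follow the Gumbel formula and its limits", {
  cal <- structure(list(mu = 10, lam = 0.5, n_calibration = 200L,
                        seed = 1L), class = "calibration_params")
  expect_equal(evalue(10, cal, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(evalue(1e6, cal, 1), 0)
  grid <- seq(0, 60, by = 2.5)
  want <- 100 * (1 - exp(-exp(-0.5 * (grid - 10))))
  expect_equal(evalue(grid, cal, 100), want, tolerance = 1e-9)
  expect_true(all(diff(evalue(grid, cal, 100)) <= 0))
  expect_equal(evalue(grid, cal, 500), 5 * evalue(grid, cal, 100),
               tolerance = 1e-12)
  expect_error(evalue(10, NULL, 1), "calibrate")
})

test_that("bias score reflects envelope composition skew", {
  prof <- pet_profile()
  # sequence drawn from the null background: nulls nearly coincide
  set.seed(99)
  s <- paste(sample(AA20, 150, TRUE, prob = prof$null_background),
             collapse = "")
  b <- bias_score(prof, s, c(1, nchar(s)))
  expect_lte(b, 0.5)
  # low-complexity envelope against the family background
  low <- strrep("K", 80)
  expect_gt(bias_score(prof, low, c(1, 80)), 0)
  # two-pass recomputation equals the reported value
  s2 <- pet_family()$members$seq[1]
  env <- viterbi_align(prof, s2)$envelope
  b2 <- bias_score(prof, s2, env)
  cnt <- table(factor(strsplit(substr(s2, env[1], env[2]), "")[[1]],
                      levels = AA20))
  null2 <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
  names(null2) <- AA20
  want <- max(0, forward_bitscore(prof, s2) -
                 forward_bitscore(prof, s2, null = null2))
  expect_equal(b2, want, tolerance = 1e-12)
  expect_error(bias_score(prof, "MKV", c(2, 1)), "envelope")
})

test_that("family members separate from their shuffled versions", {
  fam <- pet_family()
  prof <- pet_profile()
  scores <- vapply(fam$members$seq,
                   function(s) forward_bitscore(prof, s), numeric(1))
  expect_true(all(scores >= 20))
  set.seed(55)
  n_trials <- 0; n_lower <- 0
  for (s in fam$members$seq) {
    for (r in 1:5) {
      sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      n_trials <- n_trials + 1
      if (forward_bitscore(prof, sh) <
          forward_bitscore(prof, s)) n_lower <- n_lower + 1
    }
  }
  expect_gte(n_lower / n_trials, 0.95)
})

test_that("profiles serialize to text and back without loss", {
  prof <- pet_profile()
  f <- withr::local_tempfile(fileext = ".txt")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$polymer, prof$polymer)
  expect_equal(back$L, prof$L)
  expect_equal(unname(back$match_emissions),
               unname(prof$match_emissions), tolerance = 1e-15)
  expect_equal(unname(back$transitions), unname(prof$transitions),
               tolerance = 1e-15)
  expect_equal(back$calibration$mu, prof$calibration$mu, tolerance = 1e-15)
  s <- pet_family()$members$seq[1]
  expect_equal(forward_bitscore(back, s), forward_bitscore(prof, s),
               tolerance = 1e-12)
})
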