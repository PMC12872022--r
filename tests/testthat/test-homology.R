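test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwise_identity("MKV", "MKV"), 1.0)
  expect_equal(pairwise_identity("MKV", "MKA"), 2 / 3, tolerance = 1e-12)
  expect_error(pairwise_identity("", "MKV"), "empty")
  # substitution-only mutants have a known identity by construction
  set.seed(5)
  for (rep in 1:8) {
    a <- random_protein(60)
    target <- runif(1, 0.5, 0.95)
    b <- mutate_identity(a, target)
    chars_a <- strsplit(a, "")[[1]]; chars_b <- strsplit(b, "")[[1]]
    want <- mean(chars_a == chars_b)
    expect_equal(pairwise_identity(a, b), want, tolerance = 1e-12)
  }
})

test_that("greedy clustering partitions and respects the threshold", {
  s <- seq_records(c("a", "b", "c"), rep("MKVLLEAGHW", 3))
  cl <- greedy_cluster(s)
  expect_equal(length(unique(cl$representative_id)), 1L)
  expect_setequal(cl$member_id, c("a", "b", "c"))
  s2 <- seq_records(c("a", "b"), c("MKVLYEAGHWMKVLYEAGHW",
                                   "PPPPGGGGSSSSTTTTNNNN"))
  cl2 <- greedy_cluster(s2, threshold = 0.95)
  expect_equal(length(unique(cl2$representative_id)), 2L)
  expect_error(greedy_cluster(s, threshold = 0), "threshold")
  expect_error(greedy_cluster(s, threshold = 1.5), "threshold")
})

test_that("planted 97%-identity duplicates co-cluster with their source", {
  set.seed(17)
  bases <- replicate(25, random_protein(80))
  dups <- vapply(bases, function(b) mutate_identity(b, 0.97), character(1),
                 USE.NAMES = FALSE)
  recs <- seq_records(c(paste0("base_", 1:25), paste0("dup_", 1:25)),
                      c(bases, dups))
  cl <- greedy_cluster(recs, threshold = 0.95)
  # partition property
  expect_setequal(cl$member_id, recs$id)
  expect_equal(nrow(cl), nrow(recs))
  rep_of <- stats::setNames(cl$representative_id, cl$member_id)
  for (i in 1:25) {
    expect_equal(rep_of[paste0("dup_", i)], rep_of[paste0("base_", i)],
                 ignore_attr = TRUE)
  }
})

test_that("pairwise search scores match an independent Smith-Waterman DP", {
  mat <- blosum62_mat()
  tg <- seq_records("t1", "PAWHEAE")
  h <- pairwise_search(list(id = "q", seq = "HEAGAWGHEE"), tg, "PLA")
  raw_oracle <- sw_oracle("HEAGAWGHEE", "PAWHEAE", mat)
  pp <- pairwise_params()
  want_bits <- (pp$karlin_lambda * raw_oracle - log(pp$karlin_K)) / log(2)
  expect_equal(h$bitscore, want_bits, tolerance = 1e-9)
  expect_equal(h$evalue, 10 * 7 * 2^(-want_bits), tolerance = 1e-9)
  set.seed(5)
  for (rep in 1:5) {
    q <- random_protein(40); t <- random_protein(35)
    h <- pairwise_search(list(id = "q", seq = q),
                         seq_records("t", t), "PLA")
    want <- (pp$karlin_lambda * sw_oracle(q, t, mat) - log(pp$karlin_K)) /
      log(2)
    expect_equal(h$bitscore, want, tolerance = 1e-9)
  }
})

test_that("self-hits dominate and E scales linearly with database size", {
  set.seed(6)
  seqs <- replicate(5, random_protein(50))
  recs <- seq_records(paste0("t", 1:5), seqs)
  for (i in 1:5) {
    h <- pairwise_search(list(id = paste0("t", i), seq = seqs[i]), recs,
                         "PLA")
    expect_equal(h$target_id[1], paste0("t", i))
  }
  h1 <- pairwise_search(list(id = "q", seq = seqs[1]), recs, "PLA")
  h2 <- pairwise_search(list(id = "q", seq = seqs[1]), recs, "PLA",
                        db_size = 2 * sum(nchar(seqs)))
  expect_equal(h2$evalue, 2 * h1$evalue, tolerance = 1e-12)
  expect_error(pairwise_search(list(id = "q", seq = ""), recs, "PLA"),
               "empty query")
})

test_that("hit filters apply strict thresholds with HMM-only bias rule", {
  mk <- function(E, S, B, tool) {
    data.frame(protein_id = "p", polymer = "PET", tool = tool,
               bitscore = S, evalue = E, bias = B,
               stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filter_hits(mk(1e-6, 30, 2, "HMMER-like"))), 1L)
  expect_equal(nrow(filter_hits(mk(1e-6, 30, 4, "HMMER-like"))), 0L)
  expect_equal(nrow(filter_hits(mk(1e-6, 30, 4, "DIAMOND-like"))), 1L)
  # boundary equality cases: all three inequalities are strict
  expect_equal(nrow(filter_hits(mk(1e-5, 30, 0, "HMMER-like"))), 0L)
  expect_equal(nrow(filter_hits(mk(1e-6, 20, 0, "HMMER-like"))), 0L)
  expect_equal(nrow(filter_hits(mk(1e-6, 30, 3, "HMMER-like"))), 0L)
})

test_that("filtering is idempotent, order-preserving and a subset", {
  set.seed(8)
  hits <- data.frame(
    protein_id = paste0("p", 1:50), polymer = "PET",
    tool = sample(c("HMMER-like", "DIAMOND-like"), 50, TRUE),
    bitscore = runif(50, 0, 60), evalue = 10^runif(50, -12, 0),
    bias = runif(50, 0, 8), stringsAsFactors = FALSE)
  f1 <- filter_hits(hits)
  expect_identical(filter_hits(f1), f1)
  expect_true(all(f1$protein_id %in% hits$protein_id))
  expect_identical(f1$protein_id,
                   hits$protein_id[hits$protein_id %in% f1$protein_id])
})
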