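test_that("family members land inside the requested identity band", {
  fam <- generate_family(family_spec("PET", consensus_length = 80,
                                     n_members = 20,
                                     identity_band = c(0.7, 0.8),
                                     seed = 41))
  ids <- vapply(fam$members$seq,
                function(s) pairwise_identity(s, fam$consensus),
                numeric(1))
  expect_true(all(ids >= 0.7 & ids <= 0.8))
  # degenerate band: members equal the consensus
  fam1 <- generate_family(family_spec("PET", consensus_length = 50,
                                      n_members = 3,
                                      identity_band = c(1, 1), seed = 2))
  expect_true(all(fam1$members$seq == fam1$consensus))
  expect_error(generate_family(family_spec("PET", identity_band = c(0, 1))),
               "identity_band")
})

test_that("generators are deterministic given their seeds", {
  sp <- family_spec("PHB", consensus_length = 60, n_members = 5,
                    identity_band = c(0.8, 0.9), seed = 43)
  f1 <- generate_family(sp); f2 <- generate_family(sp)
  expect_identical(f1$members$seq, f2$members$seq)
  expect_identical(f1$msa, f2$msa)
  m1 <- generate_metagenome(list(f1), n_background_genes = 3, seed = 43)
  m2 <- generate_metagenome(list(f2), n_background_genes = 3, seed = 43)
  expect_identical(m1$contigs$seq, m2$contigs$seq)
  expect_identical(m1$truth, m2$truth)
  d1 <- tempfile(); d2 <- tempfile()
  r1 <- generate_reads(m1$truth, read_length = 40, insert_size = 100,
                       out_dir = d1)
  r2 <- generate_reads(m2$truth, read_length = 40, insert_size = 100,
                       out_dir = d2)
  expect_identical(readLines(r1$fastq1), readLines(r2$fastq1))
  expect_identical(readLines(r1$sam), readLines(r2$sam))
})

test_that("indel-bearing families still produce a consistent alignment", {
  fam <- generate_family(family_spec("PCL", consensus_length = 60,
                                     n_members = 6,
                                     identity_band = c(0.75, 0.92),
                                     indel_rate = 0.02, seed = 11))
  expect_equal(length(unique(nchar(fam$msa))), 1L)
  expect_identical(gsub("-", "", fam$msa), fam$members$seq)
  prof <- build_profile(fam$msa, "PCL")
  expect_gte(prof$L, 30L)
})

test_that("metagenome planting records exact coordinates and strands", {
  fam <- generate_family(family_spec("PET", consensus_length = 60,
                                     n_members = 4,
                                     identity_band = c(0.8, 0.95),
                                     seed = 47))
  mg <- generate_metagenome(list(fam), n_background_genes = 2, seed = 47)
  expect_equal(nrow(mg$truth), 6L)
  expect_setequal(unique(mg$truth$polymer), c("PET", "negative"))
  for (i in seq_len(nrow(mg$truth))) {
    tr <- mg$truth[i, ]
    ctg <- mg$contigs$seq[mg$contigs$id == tr$contig]
    sub <- substr(ctg, tr$start, tr$end)
    if (tr$strand == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_equal(sub, tr$gene_nt)
  }
  expect_error(generate_metagenome(list(), seed = 1), "at least one family")
})

test_that("read generation validates lengths and honours zero depth", {
  fam <- generate_family(family_spec("PET", consensus_length = 40,
                                     n_members = 2,
                                     identity_band = c(0.9, 1), seed = 3))
  mg <- generate_metagenome(list(fam), n_background_genes = 0, seed = 3,
                            depth_default = 4L)
  expect_error(generate_reads(mg$truth, read_length = 5000), "exceeds")
  mg$truth$depth <- c(0L, 4L)
  rd <- generate_reads(mg$truth, read_length = 60, insert_size = 100)
  expect_named(rd$expected_counts, mg$truth$gene_id[2])
  aln <- read_alignments(rd$sam)
  expect_setequal(unique(aln$ref_id), mg$truth$gene_id[2])
})
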