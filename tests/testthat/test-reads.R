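# Read emission, paired-end merging, codon-level variant counting.

test_that("merged length follows L1 + L2 - overlap", {
  # two 30-nt reads sharing an exact 10-nt overlap merge to 50 nt
  # (aperiodic amplicon so the true overlap is the only admissible one)
  amplicon <- withr::with_seed(8, paste(
    sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""))
  m1 <- substr(amplicon, 1, 30)
  m2 <- reverse_complement_chr(substr(amplicon, 21, 50))
  q <- strrep("I", 30)
  out <- merge_read_pairs(
    tibble::tibble(seq1 = m1, qual1 = q, seq2 = m2, qual2 = q),
    min_overlap = 10)
  expect_equal(out$status, "merged")
  expect_equal(nchar(out$merged), 50L)
  expect_equal(out$overlap, 10L)
  expect_equal(out$merged, amplicon)
})

test_that("pairs without an admissible overlap are rejected, not dropped", {
  q20 <- strrep("I", 20)
  out <- merge_read_pairs(
    tibble::tibble(seq1 = strrep("A", 20), qual1 = q20,
                   seq2 = strrep("G", 20), qual2 = q20),  # revcomp = C...C
    min_overlap = 10)
  expect_equal(out$status, "rejected")
  expect_true(is.na(out$merged))
  expect_equal(nrow(out), 1L)  # tallied, not silently dropped
})

test_that("overlap disagreements resolve to the higher-quality base, ties to mate 1", {
  base <- withr::with_seed(9, paste(
    sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""))
  m1 <- substr(base, 1, 25)
  m2true <- substr(base, 11, 40)
  # plant a disagreement inside the 15-nt overlap at amplicon position 20
  m1_mut <- m1; substr(m1_mut, 20, 20) <- "T"
  q_hi <- strrep(rawToChar(as.raw(40 + 33)), 25)
  q_lo <- strrep(rawToChar(as.raw(20 + 33)), 30)
  out <- merge_read_pairs(
    tibble::tibble(seq1 = m1_mut, qual1 = q_hi,
                   seq2 = reverse_complement_chr(m2true), qual2 = q_lo),
    min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(out$status, "merged")
  expect_equal(substr(out$merged, 20, 20), "T")  # mate 1 wins on quality
  # equal qualities: tie also goes to mate 1
  out2 <- merge_read_pairs(
    tibble::tibble(seq1 = m1_mut, qual1 = q_hi,
                   seq2 = reverse_complement_chr(m2true),
                   qual2 = strrep(rawToChar(as.raw(40 + 33)), 30)),
    min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(substr(out2$merged, 20, 20), "T")
})

test_that("sequence/quality length mismatch is a format error", {
  expect_error(
    merge_read_pairs(tibble::tibble(seq1 = "ACGT", qual1 = "III",
                                    seq2 = "ACGT", qual2 = "IIII")),
    "length mismatch")
})

test_that("codon counting translates the target codon and filters damaged reads", {
  ref <- toy_reference()
  # 10 reads with TGG (Trp) at residue 15, 5 reference reads
  mut <- ref; substr(mut, 43, 45) <- "TGG"
  counts <- count_variants(c(rep(mut, 10), rep(ref, 5)), ref, 15)
  expect_equal(counts$count[counts$amino_acid == "W"], 10L)
  ref_aa <- reference_protein(30)[15]
  expect_equal(counts$count[counts$amino_acid == ref_aa], 5L)
  expect_equal(attr(counts, "n_discarded"), 0L)
  # a 1-nt deletion breaks the expected span and is discarded
  del <- paste0(substr(ref, 1, 10), substr(ref, 12, nchar(ref)))
  counts2 <- count_variants(c(rep(mut, 3), del), ref, 15)
  expect_equal(sum(counts2$count), 3L)
  expect_equal(attr(counts2, "n_discarded"), 1L)
  # N in the target codon is discarded; stop codons tally under "*"
  amb <- ref; substr(amb, 44, 44) <- "N"
  stp <- ref; substr(stp, 43, 45) <- "TAA"
  counts3 <- count_variants(c(amb, stp), ref, 15)
  expect_equal(attr(counts3, "n_discarded"), 1L)
  expect_equal(counts3$count[counts3$amino_acid == "*"], 1L)
  # conservation: counts + discards = reads, in every case
  for (ct in list(counts, counts2, counts3)) {
    expect_equal(sum(ct$count) + attr(ct, "n_discarded"), attr(ct, "n_reads"))
  }
})

test_that("the standard genetic code is applied to sense and stop codons", {
  gc <- Biostrings::GENETIC_CODE
  expect_equal(unname(gc[["TGG"]]), "W")
  ref <- toy_reference()
  for (codon in c("TAA", "TAG", "TGA")) {
    mut <- ref; substr(mut, 43, 45) <- codon
    ct <- count_variants(mut, ref, 15)
    expect_equal(ct$count[ct$amino_acid == "*"], 1L)
  }
})

test_that("emit -> merge -> count round trip is exact at error-free settings", {
  ref <- toy_reference()
  tab <- tibble::tibble(residue_index = c(15L, 15L, 16L),
                        alt_aa = c("W", reference_protein(30)[15], "K"),
                        count = c(10L, 5L, 7L))
  pairs <- emit_reads(tab, ref, read_length = 60, seed = 4)
  expect_equal(nrow(pairs), sum(tab$count))  # conservation of read pairs
  merged <- merge_read_pairs(pairs, min_overlap = 10)
  expect_true(all(merged$status == "merged"))
  c15 <- count_variants(merged, ref, 15)
  expect_equal(c15$count[c15$amino_acid == "W"], 10L)
  expect_equal(c15$count[c15$amino_acid == reference_protein(30)[15]], 5L)
  # residue-16 mutant reads mismatch the residue-15 window and are discarded
  expect_equal(sum(c15$count) + attr(c15, "n_discarded"), nrow(pairs))
  c16 <- count_variants(merged, ref, 16)
  expect_equal(c16$count[c16$amino_acid == "K"], 7L)
  # zero-count variants emit no reads
  empty <- emit_reads(tibble::tibble(residue_index = 15L, alt_aa = "W",
                                     count = 0L), ref, read_length = 60)
  expect_equal(nrow(empty), 0L)
})

test_that("fastq round trip through files preserves pairs", {
  ref <- toy_reference()
  pairs <- emit_reads(tibble::tibble(residue_index = 15L, alt_aa = "W",
                                     count = 4L), ref, read_length = 60,
                      seed = 2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs, f1, f2)
  back <- read_fastq_pairs(f1, f2)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
})

test_that("reads that fall outside the amplicon span are refused", {
  ref <- toy_reference()  # 90 nt
  expect_error(emit_reads(tibble::tibble(residue_index = 1L, alt_aa = "W",
                                         count = 1L), ref, read_length = 60),
               "not covered")
  expect_error(count_variants(character(), ref, 31), "not covered")
})
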