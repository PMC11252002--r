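test_that("transcriptome simulation is deterministic and emits valid ORFs", {
  a <- simulate_transcriptome(10, c(50, 100), seed = 1)
  b <- simulate_transcriptome(10, c(50, 100), seed = 1)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_cds_fasta(a, f1); write_cds_fasta(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(a$sequence,
                         simulate_transcriptome(10, c(50, 100), seed = 2)$sequence))

  expect_true(all(nchar(a$sequence) %% 3 == 0))
  expect_true(all(substr(a$sequence, 1, 3) == "ATG"))
  last <- substring(a$sequence, nchar(a$sequence) - 2)
  expect_true(all(last %in% stop_codons()))
  # single terminal stop: no internal stop codons
  internal_stops <- vapply(a$sequence, function(s) {
    cc <- count_codons(substr(s, 1, nchar(s) - 3))
    sum(cc[stop_codons()])
  }, numeric(1))
  expect_true(all(internal_stops == 0))
})

test_that("planted codon bias raises the planted codon's content", {
  tx <- simulate_transcriptome(
    200, c(100, 300),
    planted_sets = list(list(name = "b", fraction = 0.2, codon = "GTG",
                             multiplier = 4)),
    seed = 7
  )
  content <- content_profiles(tx, "codon")
  planted <- !is.na(tx$planted_set)
  expect_equal(sum(planted), 40)
  expect_gt(mean(content[planted, "GTG"]), mean(content[!planted, "GTG"]))
  # and clearly so: planted mean is about 4x the weight on one of 61+3 slots
  expect_gt(mean(content[planted, "GTG"]), 2 * mean(content[!planted, "GTG"]))
})

test_that("transcriptome simulation validates weights and planted sets", {
  expect_error(simulate_transcriptome(5, base_codon_weights = c(GTG = 0)),
               "sums to zero")
  expect_error(simulate_transcriptome(5, base_codon_weights = c(XXX = 1)),
               "sense codons")
  expect_error(
    simulate_transcriptome(5, planted_sets = list(
      list(name = "b", fraction = 1.2, codon = "GTG", multiplier = 2))))
})

test_that("fold-change tables plant the requested stratified shift", {
  tx <- simulate_transcriptome(300, c(100, 300), seed = 2)
  null_fc <- simulate_fc_table(tx, "Val", mean_shift = 0, noise_sd = 0.3,
                               seed = 3)
  m_in <- mean(null_fc$log2fc[null_fc$in_target])
  m_out <- mean(null_fc$log2fc[!null_fc$in_target])
  expect_lt(abs(m_in - m_out), 3 * 0.3 / sqrt(sum(null_fc$in_target)))

  shifted <- simulate_fc_table(tx, "Val", mean_shift = -0.5, noise_sd = 0.3,
                               seed = 3)
  expect_lt(mean(shifted$log2fc[shifted$in_target]), -0.3)
  expect_identical(shifted,
                   simulate_fc_table(tx, "Val", mean_shift = -0.5,
                                     noise_sd = 0.3, seed = 3))
  expect_error(simulate_fc_table(tx, "Xyz"), "unknown amino acid")
})

test_that("rpf simulation conserves read totals and honours the null", {
  tx <- simulate_transcriptome(30, c(60, 120), seed = 4)
  reads <- simulate_rpf_dataset(tx, reads_per_transcript = 50, seed = 5)
  per_tx <- tapply(reads$count, reads$transcript_id, sum)
  expect_true(all(per_tx == 50))
  expect_equal(sum(reads$count), 30 * 50)
  expect_identical(reads, simulate_rpf_dataset(tx, reads_per_transcript = 50,
                                               seed = 5))

  # null: per-codon occupancy matches positional codon frequency
  tal <- naive_occupancy_tally(reads, tx, 15)
  frac <- tal / sum(tal)
  # positional frequency of codons at valid offset-15 sites
  pos_tal <- naive_occupancy_tally(uniform_reads(tx, 30), tx, 15)
  pos_frac <- pos_tal / sum(pos_tal)
  se <- sqrt(pos_frac * (1 - pos_frac) / sum(tal))
  expect_true(all(abs(frac - pos_frac) < 4 * se + 1e-3))
})

test_that("rpf simulation skips too-short transcripts with a warning", {
  tx <- rbind(toy_records(),
              data.frame(gene_id = "gL", transcript_id = "tL",
                         sequence = paste0("ATG", strrep("GTG", 40), "TAA")))
  expect_warning(reads <- simulate_rpf_dataset(tx, read_length = 30,
                                               reads_per_transcript = 10,
                                               seed = 1),
                 "shorter than the read length")
  expect_setequal(unique(reads$transcript_id), "tL")
})

test_that("tRNA count simulation is deterministic and validates replicates", {
  s1 <- simulate_trna_counts(seed = 8)
  s2 <- simulate_trna_counts(seed = 8)
  expect_identical(s1, s2)
  expect_error(simulate_trna_counts(replicates = 1), ">= 2 replicates")
  expect_error(simulate_trna_counts(
    planted = list(list(amino_acid = "Val", anticodon = "ZZZ", fold = 2))),
    "unknown anticodon")
  planted <- simulate_trna_counts(
    planted = list(list(amino_acid = "Val", anticodon = "CAC", fold = 2)),
    seed = 8)
  val <- planted$counts$anticodon == "CAC"
  res_cols <- names(planted$conditions)[planted$conditions == "RES"]
  sens_cols <- names(planted$conditions)[planted$conditions == "SENS"]
  expect_gt(mean(as.matrix(planted$counts[val, res_cols])),
            1.5 * mean(as.matrix(planted$counts[val, sens_cols])))
})

test_that("expression matrices have the requested shape and planted shift", {
  sim <- simulate_expression_matrix(50, 12, signature = sprintf("g%04d", 1:10),
                                    n_high = 3, shift = 1, seed = 10)
  expect_equal(dim(sim$counts), c(50, 12))
  expect_equal(sim$high_samples, sprintf("s%03d", 1:3))
  sig_rows <- rownames(sim$counts) %in% sprintf("g%04d", 1:10)
  expect_gt(mean(sim$counts[sig_rows, 1:3]), mean(sim$counts[sig_rows, 4:12]))
  expect_error(simulate_expression_matrix(10, 5, signature = "gX"),
               "outside the gene universe")
})
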