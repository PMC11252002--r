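# Fixtures built in code: tiny CDS tables, isodecoder count tables and
# read tables used across the module tests.

toy_records <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC", "gD"),
    transcript_id = c("tA", "tB", "tC", "tD"),
    sequence = c(
      "ATGGTGGTGGTTTAA",          # Met Val Val Val stop
      "ATGCTGCTGCTGCTGTAA",       # Met Leu x4 stop
      "ATGGATGACGATTAA",          # Met Asp Asp Asp stop
      "ATGAAAAAGAAATAA"           # Met Lys Lys Lys stop
    )
  )
}

# isodecoder table for the aggregation worked example, two samples
toy_isodecoders <- function() {
  df <- data.frame(
    isodecoder_id = c("tRNA-Val-CAC-1", "tRNA-Val-CAC-2", "tRNA-Val-AAC-1"),
    amino_acid = c("Val", "Val", "Val"),
    anticodon = c("CAC", "CAC", "AAC")
  )
  df[c("s1", "s2", "r1", "r2")] <- cbind(
    c(10, 5, 5), c(10, 5, 5), c(20, 10, 10), c(20, 10, 10)
  )
  df
}

toy_conditions <- function() {
  c(s1 = "SENS", s2 = "SENS", r1 = "RES", r2 = "RES")
}

# uniform single-count coverage of every CDS position for given records
uniform_reads <- function(records, read_length = 1L) {
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    n <- nchar(records$sequence[i])
    data.frame(transcript_id = records$transcript_id[i],
               pos = 0:(n - read_length), length = read_length, count = 1L)
  }))
}

# brute-force per-offset codon tally: the independent occupancy oracle
naive_occupancy_tally <- function(reads, records, offset) {
  seqs <- stats::setNames(records$sequence, records$transcript_id)
  tal <- stats::setNames(numeric(length(sense_codons())), sense_codons())
  for (i in seq_len(nrow(reads))) {
    s <- seqs[[reads$transcript_id[i]]]
    p <- reads$pos[i] + offset
    idx <- p %/% 3
    if (p < 0 || idx >= nchar(s) %/% 3) next
    codon <- substr(s, idx * 3 + 1, idx * 3 + 3)
    if (codon %in% names(tal)) tal[codon] <- tal[codon] + reads$count[i]
  }
  tal
}

# closed-form pooled two-sample t-test: the independent differential oracle
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * pt(-abs(t), df = nx + ny - 2))
}
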