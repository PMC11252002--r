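# Ribosome-profiling downstream statistics: metagene density profiles,
# site-resolved differential codon occupancy of footprint 5' ends
# (E/P/A-site offsets 9/12/15 nt), and codon-content-stratified
# fold-change comparison of differential tables.

# transcript annotation helper: CDS bounds default to the whole transcript
rpf_transcript_table <- function(reads, transcripts = NULL) {
  if (is.null(transcripts)) {
    stop("transcripts annotation required (transcript_id, length; optional cds_start, cds_end)")
  }
  stopifnot(all(c("transcript_id", "length") %in% names(transcripts)))
  if (is.null(transcripts$cds_start)) transcripts$cds_start <- 0L
  if (is.null(transcripts$cds_end)) transcripts$cds_end <- transcripts$length
  missing <- setdiff(unique(reads$transcript_id), transcripts$transcript_id)
  if (length(missing)) {
    stop(sprintf("reads reference unannotated transcripts: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  transcripts
}

#' Transcript annotation for a simulated (all-CDS) transcriptome
#'
#' @param records CDS records data.frame.
#' @return data.frame (`transcript_id`, `length`, `cds_start`, `cds_end`)
#'   suitable for [metagene_profile()].
#' @export
cds_annotation <- function(records) {
  data.frame(transcript_id = records$transcript_id,
             length = nchar(records$sequence),
             cds_start = 0L,
             cds_end = nchar(records$sequence))
}

#' Metagene footprint density profile
#'
#' Per transcript, the per-nucleotide 5'-end density is divided by that
#' transcript's mean CDS density (so the profile is invariant to
#' per-transcript sequencing depth), the CDS is rescaled to `n_cds_bins`
#' equal-width bins, and flanking UTR windows are kept at nucleotide
#' resolution. Transcripts with no CDS reads are excluded from the average
#' and counted.
#'
#' @param reads data.frame (`transcript_id`, `pos` — 0-based 5' end,
#'   `length`, `count`).
#' @param transcripts Annotation data.frame (`transcript_id`, `length`,
#'   optional `cds_start`, `cds_end`, 0-based half-open).
#' @param n_cds_bins Number of CDS bins (default 30).
#' @param utr_window_nt Nucleotides of UTR flank to keep on each side
#'   (default 0; truncated to what each transcript has).
#' @return data.frame (`region` = utr5/cds/utr3, `bin`, `mean_density`)
#'   with attribute `n_transcripts` (contributing) and `n_excluded`.
#' @export
metagene_profile <- function(reads, transcripts, n_cds_bins = 30L,
                             utr_window_nt = 0L) {
  transcripts <- rpf_transcript_table(reads, transcripts)
  split_reads <- split(reads, reads$transcript_id)
  prof_cds <- matrix(NA_real_, length(split_reads), n_cds_bins)
  prof_u5 <- matrix(NA_real_, length(split_reads), utr_window_nt)
  prof_u3 <- matrix(NA_real_, length(split_reads), utr_window_nt)
  n_excluded <- 0L
  for (i in seq_along(split_reads)) {
    r <- split_reads[[i]]
    tx <- transcripts[match(names(split_reads)[i], transcripts$transcript_id), ]
    dens <- numeric(tx$length)
    ok <- r$pos >= 0 & r$pos < tx$length
    dens[r$pos[ok] + 1L] <- dens[r$pos[ok] + 1L] + r$count[ok]
    cds_idx <- (tx$cds_start + 1L):tx$cds_end
    mean_cds <- mean(dens[cds_idx])
    if (mean_cds == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    norm <- dens / mean_cds
    cds_norm <- norm[cds_idx]
    bin <- pmin(floor((seq_along(cds_norm) - 1L) / length(cds_norm) *
                        n_cds_bins) + 1L, n_cds_bins)
    prof_cds[i, ] <- tapply(cds_norm, factor(bin, levels = seq_len(n_cds_bins)),
                            mean, default = 0)
    if (utr_window_nt > 0) {
      u5 <- rev(norm[seq_len(tx$cds_start)]) # nearest-to-CDS first
      n5 <- min(length(u5), utr_window_nt)
      if (n5 > 0) prof_u5[i, seq_len(n5)] <- u5[seq_len(n5)]
      u3 <- norm[seq(tx$cds_end + 1L, length.out = tx$length - tx$cds_end)]
      n3 <- min(length(u3), utr_window_nt)
      if (n3 > 0) prof_u3[i, seq_len(n3)] <- u3[seq_len(n3)]
    }
  }
  rows <- data.frame(region = "cds", bin = seq_len(n_cds_bins),
                     mean_density = colMeans(prof_cds, na.rm = TRUE))
  if (utr_window_nt > 0) {
    rows <- rbind(
      data.frame(region = "utr5", bin = -(utr_window_nt:1),
                 mean_density = rev(colMeans(prof_u5, na.rm = TRUE))),
      rows,
      data.frame(region = "utr3", bin = n_cds_bins + seq_len(utr_window_nt),
                 mean_density = colMeans(prof_u3, na.rm = TRUE))
    )
  }
  rows$mean_density[is.nan(rows$mean_density)] <- NA_real_
  structure(rows,
            n_transcripts = length(split_reads) - n_excluded,
            n_excluded = n_excluded)
}

# per-offset codon tally of one read set; returns counts over sense codons
tally_offset_codons <- function(reads, seqs, cds_start, offset) {
  tal <- stats::setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  site <- reads$pos + offset
  j <- site - cds_start[reads$transcript_id]
  codon_idx <- j %/% 3L # codon containing the site nucleotide
  s <- seqs[reads$transcript_id]
  n_codons <- nchar(s) %/% 3L
  ok <- j >= 0 & codon_idx < n_codons
  codons <- substring(s[ok], codon_idx[ok] * 3L + 1L, codon_idx[ok] * 3L + 3L)
  keep <- codons %in% SENSE_CODONS
  add <- rowsum(reads$count[ok][keep], group = codons[keep])
  tal[rownames(add)] <- add[, 1]
  tal
}

#' Differential codon occupancy at footprint site offsets
#'
#' For each configured offset (defaults 9, 12, 15 nt from the read 5' end:
#' the E, P and A sites), each read contributes its count to the codon
#' containing the nucleotide at `5' end + offset`. Per condition the tally
#' is normalised to occupancy fractions (summing to 1 over sense codons);
#' the shift is `log2((fraction_A + eps) / (fraction_B + eps))` and
#' `z_shift` standardises the shifts across codons within each offset.
#'
#' @param reads_a,reads_b Read tables for the two conditions
#'   (`transcript_id`, `pos`, `length`, `count`).
#' @param records CDS records shared by both datasets (sequences supply the
#'   codon at each site).
#' @param offsets Named integer offsets, default `c(E = 9, P = 12, A = 15)`.
#' @param eps Pseudo-fraction guarding against zero counts (default 1e-6).
#' @return data.frame (`site`, `offset`, `codon`, `fraction_a`,
#'   `fraction_b`, `log2_shift`, `z_shift`).
#' @export
codon_occupancy <- function(reads_a, reads_b, records,
                            offsets = c(E = 9L, P = 12L, A = 15L),
                            eps = 1e-6) {
  validate_cds(records)
  if (max(offsets) + 3L > min(c(reads_a$length, reads_b$length))) {
    stop("an offset extends beyond the shortest read")
  }
  seqs <- stats::setNames(records$sequence, records$transcript_id)
  cds_start <- stats::setNames(rep(0L, nrow(records)), records$transcript_id)
  if (is.null(names(offsets))) names(offsets) <- as.character(offsets)
  out <- lapply(seq_along(offsets), function(k) {
    ta <- tally_offset_codons(reads_a, seqs, cds_start, offsets[k])
    tb <- tally_offset_codons(reads_b, seqs, cds_start, offsets[k])
    fa <- ta / sum(ta)
    fb <- tb / sum(tb)
    shift <- log2((fa + eps) / (fb + eps))
    data.frame(site = names(offsets)[k], offset = unname(offsets[k]),
               codon = SENSE_CODONS,
               fraction_a = unname(fa), fraction_b = unname(fb),
               log2_shift = unname(shift),
               z_shift = unname((shift - mean(shift)) / stats::sd(shift)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Content-stratified fold-change comparison
#'
#' Restricts a differential table to significant genes, ranks them by one
#' amino acid's content, and compares the log2 fold changes of the top
#' content quartile against the bottom quartile with a two-sided unpaired
#' t-test. Quartiles are recomputed within the significant set (the
#' analysed population), using the same rank-based machinery as the
#' transcriptome background.
#'
#' @param diff Differential table (`gene_id`, `log2fc`, `significant`).
#' @param content Amino-acid content matrix from [content_profiles()]
#'   covering the differential table's genes.
#' @param amino_acid Amino acid to stratify on (three-letter code).
#' @param significant_only Restrict to flagged genes (default `TRUE`).
#' @param frac Stratum fraction (default 0.25).
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return List of class `stratified_fc`: `amino_acid`, data.frames `top`
#'   and `bottom` (`gene_id`, `content`, `log2fc`), `t_stat`, `p`, `n_sig`.
#' @export
stratify_fc <- function(diff, content, amino_acid,
                        significant_only = TRUE, frac = 0.25,
                        var_equal = TRUE) {
  stopifnot(amino_acid %in% colnames(content))
  d <- diff[diff$gene_id %in% rownames(content), ]
  if (significant_only) d <- d[d$significant, ]
  if (nrow(d) < 4) stop("fewer than 4 genes after filtering")
  vals <- content[d$gene_id, amino_acid]
  top_ids <- top_fraction(vals, d$gene_id, frac = frac, decreasing = TRUE)
  bottom_ids <- top_fraction(vals, d$gene_id, frac = frac, decreasing = FALSE)
  pick <- function(ids) {
    data.frame(gene_id = ids,
               content = content[ids, amino_acid],
               log2fc = d$log2fc[match(ids, d$gene_id)],
               row.names = NULL)
  }
  top <- pick(top_ids); bottom <- pick(bottom_ids)
  tt <- safe_t_test(top$log2fc, bottom$log2fc, var_equal = var_equal)
  structure(list(amino_acid = amino_acid, top = top, bottom = bottom,
                 t_stat = tt$t, p = tt$p, n_sig = nrow(d)),
            class = "stratified_fc")
}

#' @export
print.stratified_fc <- function(x, ...) {
  cat(sprintf(
    "stratified_fc [%s]: %d significant genes; top/bottom %d vs %d; t = %.3f, p = %.3g\n",
    x$amino_acid, x$n_sig, nrow(x$top), nrow(x$bottom), x$t_stat, x$p
  ))
  invisible(x)
}

#' Fold-change matrix for candidate genes across omic layers
#'
#' @param diff_tables Named list of differential tables (`gene_id`,
#'   `log2fc`, `significant`).
#' @param genes Character vector of candidate gene ids (present in at
#'   least one table).
#' @return List with matrices `log2fc` and `significant` (genes x tables);
#'   entries for genes absent from a table are `NA`.
#' @export
candidate_fc_matrix <- function(diff_tables, genes) {
  stopifnot(length(diff_tables) >= 1, !is.null(names(diff_tables)))
  fc <- sapply(diff_tables, function(d) d$log2fc[match(genes, d$gene_id)])
  sig <- sapply(diff_tables, function(d) d$significant[match(genes, d$gene_id)])
  fc <- matrix(fc, nrow = length(genes),
               dimnames = list(genes, names(diff_tables)))
  sig <- matrix(sig, nrow = length(genes),
                dimnames = list(genes, names(diff_tables)))
  if (all(rowSums(!is.na(fc)) == 0)) stop("no candidate found in any table")
  list(log2fc = fc, significant = sig)
}
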