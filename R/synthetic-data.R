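# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on data from these functions alone: coding sequences with
# planted codon bias, differential tables with planted content-stratified
# shifts, ribosome-footprint reads with a planted site-specific pause, tRNA
# isodecoder count tables with planted isoacceptor fold changes, and
# count matrices with planted signature-high samples. Each generator is a
# pure function of its arguments including `seed`: per-unit sub-seeds are
# drawn from the top-level seed by unit index, so results are independent
# of iteration order.

#' Simulate a coding transcriptome with planted codon bias
#'
#' Codons are sampled i.i.d. per position from `base_codon_weights`
#' (uniform over the 61 sense codons by default): each CDS starts with ATG,
#' ends with a single stop codon, and has a total length drawn uniformly
#' from `cds_length_range` (in codons). For genes assigned to a planted
#' set, the planted codon's sampling weight is multiplied by its bias, so
#' sequences remain valid ORFs and the bias magnitude stays interpretable.
#'
#' @param n_genes Number of genes (one transcript each).
#' @param cds_length_range Length range in codons, start and stop included;
#'   default `c(100, 600)`.
#' @param base_codon_weights Named non-negative weights over the 61 sense
#'   codons; unnamed codons get weight 0. Default: uniform.
#' @param planted_sets List of planted biases, each a list with elements
#'   `name`, `fraction` (of genes, in (0,1)), `codon`, `multiplier` (> 0).
#'   Sets are disjoint; genes are assigned at random.
#' @param seed Integer seed.
#' @return data.frame of CDS records (`gene_id`, `transcript_id`,
#'   `sequence`, `planted_set` — `NA` for unplanted genes).
#' @export
#' @examples
#' tx <- simulate_transcriptome(20, c(50, 80), seed = 1)
simulate_transcriptome <- function(n_genes,
                                   cds_length_range = c(100, 600),
                                   base_codon_weights = NULL,
                                   planted_sets = list(),
                                   seed = 1L) {
  stopifnot(n_genes >= 1, length(cds_length_range) == 2,
            cds_length_range[1] >= 3, diff(cds_length_range) >= 0)
  w <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (!is.null(base_codon_weights)) {
    if (is.null(names(base_codon_weights)) ||
        !all(names(base_codon_weights) %in% SENSE_CODONS)) {
      stop("base_codon_weights must be named by sense codons")
    }
    if (any(base_codon_weights < 0)) stop("codon weights must be non-negative")
    w[] <- 0
    w[names(base_codon_weights)] <- base_codon_weights
  }
  if (sum(w) <= 0) stop("codon weight vector sums to zero")
  for (ps in planted_sets) {
    stopifnot(ps$fraction > 0, ps$fraction < 1, ps$multiplier > 0,
              ps$codon %in% SENSE_CODONS)
  }

  gene_id <- sprintf("g%04d", seq_len(n_genes))
  planted <- rep(NA_character_, n_genes)
  gene_seeds <- split_seeds(seed, n_genes + 1L)
  # assignment of genes to planted sets from its own substream
  assignment <- with_seed(gene_seeds[n_genes + 1L], {
    pool <- seq_len(n_genes)
    out <- list()
    for (ps in planted_sets) {
      size <- ceiling(ps$fraction * n_genes)
      if (size > length(pool)) stop("planted sets exhaust the gene universe")
      pick <- sample(pool, size)
      pool <- setdiff(pool, pick)
      out[[ps$name]] <- pick
    }
    out
  })
  weights_of <- stats::setNames(vector("list", length(planted_sets)),
                                vapply(planted_sets, `[[`, "", "name"))
  for (ps in planted_sets) {
    wp <- w
    wp[ps$codon] <- wp[ps$codon] * ps$multiplier
    weights_of[[ps$name]] <- wp
    planted[assignment[[ps$name]]] <- ps$name
  }

  sequence <- character(n_genes)
  for (i in seq_len(n_genes)) {
    wi <- if (is.na(planted[i])) w else weights_of[[planted[i]]]
    sequence[i] <- with_seed(gene_seeds[i], {
      len <- sample(seq(cds_length_range[1], cds_length_range[2]), 1)
      body <- sample(SENSE_CODONS, len - 2L, replace = TRUE, prob = wi)
      stop_codon <- sample(STOP_CODONS, 1)
      paste(c("ATG", body, stop_codon), collapse = "")
    })
  }
  data.frame(gene_id = gene_id,
             transcript_id = sprintf("t%04d", seq_len(n_genes)),
             sequence = sequence, planted_set = planted)
}

#' Simulate a differential table with a content-stratified shift
#'
#' Assigns per-gene log2 fold changes: genes in the target stratum (top or
#' bottom content quartile of `amino_acid` across `records`) receive
#' `Normal(mean_shift, noise_sd)`, all others `Normal(0, noise_sd)`.
#' Nominal p-values come from the two-sided normal tail of `log2fc /
#' noise_sd`; significance flags mark the `n_significant` genes with the
#' largest absolute fold change.
#'
#' @param records CDS records (one transcript per gene).
#' @param amino_acid Target amino acid, three-letter code (e.g. `"Val"`).
#' @param stratum `"top"` or `"bottom"` content quartile.
#' @param mean_shift Planted mean shift, log2 units (0 = null table).
#' @param noise_sd Noise standard deviation, log2 units (> 0).
#' @param n_significant Number of genes flagged significant.
#' @param seed Integer seed.
#' @return data.frame (`gene_id`, `log2fc`, `p`, `p_adj`, `significant`,
#'   `in_target`).
#' @export
simulate_fc_table <- function(records, amino_acid = "Val",
                              stratum = c("top", "bottom"),
                              mean_shift = -0.5, noise_sd = 0.3,
                              n_significant = NULL, seed = 1L) {
  stratum <- match.arg(stratum)
  if (!amino_acid %in% AMINO_ACIDS) {
    stop(sprintf("unknown amino acid '%s'", amino_acid))
  }
  stopifnot(noise_sd > 0)
  content <- content_profiles(records, level = "amino_acid")
  target <- top_fraction(content[, amino_acid], rownames(content),
                         frac = 0.25, decreasing = stratum == "top")
  ids <- rownames(content)
  n <- length(ids)
  if (is.null(n_significant)) n_significant <- ceiling(0.3 * n)
  stopifnot(n_significant <= n)
  in_target <- ids %in% target
  fc <- with_seed(seed, {
    stats::rnorm(n, mean = ifelse(in_target, mean_shift, 0), sd = noise_sd)
  })
  p <- 2 * stats::pnorm(-abs(fc) / noise_sd)
  sig_ids <- top_fraction(abs(fc), ids, frac = n_significant / n)
  data.frame(gene_id = ids, log2fc = fc, p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             significant = ids %in% sig_ids,
             in_target = in_target)
}

#' Simulate a ribosome-footprint dataset with an optional planted pause
#'
#' Read 5' ends are placed uniformly over the positions at which a full
#' read fits inside the CDS, then importance-resampled so that reads whose
#' in-frame codon at `pause_offset` nt from the 5' end equals `pause_codon`
#' are `fold_enrichment` times as likely. `fold_enrichment = 1` (or a NULL
#' pause codon) gives the uniform null.
#'
#' @param records CDS records; transcripts shorter than `read_length` are
#'   skipped with a warning.
#' @param pause_codon Codon to enrich, or `NULL` for no pause.
#' @param pause_offset Offset (nt) from the read 5' end to the first
#'   nucleotide of the paused site codon; default 15 (A site).
#' @param fold_enrichment Multiplier >= 1 on read sampling weight.
#' @param read_length Footprint length in nt (default 30).
#' @param reads_per_transcript Reads sampled per transcript.
#' @param seed Integer seed.
#' @return data.frame of collapsed reads (`transcript_id`, `pos` — 0-based
#'   5'-end position, `length`, `count`).
#' @export
simulate_rpf_dataset <- function(records, pause_codon = NULL,
                                 pause_offset = 15L, fold_enrichment = 1,
                                 read_length = 30L,
                                 reads_per_transcript = 100L, seed = 1L) {
  stopifnot(fold_enrichment >= 1, read_length >= pause_offset + 3L)
  validate_cds(records)
  if (!is.null(pause_codon)) stopifnot(pause_codon %in% SENSE_CODONS)
  n <- nrow(records)
  len <- nchar(records$sequence)
  short <- len < read_length
  if (any(short)) {
    warning(sprintf("%d transcript(s) shorter than the read length skipped",
                    sum(short)))
  }
  gene_seeds <- split_seeds(seed, n)
  out <- vector("list", n)
  for (i in which(!short)) {
    positions <- 0:(len[i] - read_length) # 0-based valid 5' ends
    wgt <- rep(1, length(positions))
    if (!is.null(pause_codon) && fold_enrichment > 1) {
      site <- positions + pause_offset
      codon_idx <- site %/% 3L # codon containing the site nt
      codons <- substring(records$sequence[i],
                          codon_idx * 3L + 1L, codon_idx * 3L + 3L)
      wgt[codons == pause_codon] <- fold_enrichment
    }
    picked <- with_seed(gene_seeds[i], {
      sample(positions, reads_per_transcript, replace = TRUE,
             prob = wgt / sum(wgt))
    })
    tab <- table(picked)
    out[[i]] <- data.frame(
      transcript_id = records$transcript_id[i],
      pos = as.integer(names(tab)),
      length = read_length,
      count = as.integer(tab)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a tRNA isodecoder count table
#'
#' One isodecoder family per sense-codon anticodon, `n_isodecoders` gene
#' copies each. Baseline expression per isodecoder is lognormal around
#' `base_mean` (shared across samples); per-sample counts add lognormal
#' noise of log-sd `sdlog`. Planted anticodons have their expected counts
#' multiplied by `fold` in the second (RES) condition.
#'
#' @param planted List of planted effects, each a list with `amino_acid`
#'   (three-letter), `anticodon`, `fold` (> 0).
#' @param n_isodecoders Isodecoder gene copies per anticodon (default 3).
#' @param replicates Replicates per condition (>= 2).
#' @param base_mean Baseline expected count (default 500).
#' @param sdlog Lognormal noise log-sd (default 0.25).
#' @param seed Integer seed.
#' @return List with `counts` (data.frame: `isodecoder_id`, `amino_acid`,
#'   `anticodon`, one column per sample) and `conditions` (named vector,
#'   `SENS`/`RES` per sample).
#' @export
simulate_trna_counts <- function(planted = list(), n_isodecoders = 3L,
                                 replicates = 3L, base_mean = 500,
                                 sdlog = 0.25, seed = 1L) {
  if (replicates < 2) stop("differential testing requires >= 2 replicates")
  for (p in planted) {
    stopifnot(p$fold > 0)
    if (!p$anticodon %in% codon_to_anticodon(SENSE_CODONS)) {
      stop(sprintf("unknown anticodon '%s'", p$anticodon))
    }
  }
  anticodons <- codon_to_anticodon(SENSE_CODONS)
  aa <- CODON_AA[SENSE_CODONS]
  fold <- stats::setNames(rep(1, length(anticodons)), anticodons)
  for (p in planted) fold[p$anticodon] <- p$fold

  n_rows <- length(anticodons) * n_isodecoders
  samples <- c(paste0("SENS_", seq_len(replicates)),
               paste0("RES_", seq_len(replicates)))
  conditions <- stats::setNames(rep(c("SENS", "RES"), each = replicates),
                                samples)
  counts <- with_seed(seed, {
    base <- stats::rlnorm(n_rows, meanlog = log(base_mean), sdlog = 0.5)
    m <- matrix(0, n_rows, length(samples))
    f <- rep(unname(fold), each = n_isodecoders)
    for (j in seq_along(samples)) {
      mu <- if (conditions[j] == "RES") base * f else base
      m[, j] <- stats::rlnorm(n_rows, meanlog = log(mu), sdlog = sdlog)
    }
    round(m)
  })
  df <- data.frame(
    isodecoder_id = paste0("tRNA-", rep(aa, each = n_isodecoders), "-",
                           rep(anticodons, each = n_isodecoders), "-",
                           rep(seq_len(n_isodecoders), length(anticodons))),
    amino_acid = rep(unname(aa), each = n_isodecoders),
    anticodon = rep(anticodons, each = n_isodecoders)
  )
  df[samples] <- counts
  list(counts = df, conditions = conditions)
}

#' Simulate a gene-by-sample count matrix with signature-high samples
#'
#' Negative-binomial counts (dispersion `dispersion`, so variance
#' `mu + dispersion * mu^2`) around lognormal per-gene baselines. In the
#' designated high samples, signature genes' expected counts are multiplied
#' by `2^shift`.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param signature Character vector of signature gene ids (subset of
#'   `g0001..`), or indices.
#' @param n_high Number of signature-high samples (the first `n_high`
#'   columns).
#' @param shift Planted log2 shift (0 = null).
#' @param dispersion NB dispersion (default 0.1).
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix with dimnames) and
#'   `high_samples` (character vector).
#' @export
simulate_expression_matrix <- function(n_genes, n_samples, signature = NULL,
                                       n_high = 0L, shift = 0,
                                       dispersion = 0.1, seed = 1L) {
  stopifnot(n_high <= n_samples)
  genes <- sprintf("g%04d", seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))
  if (is.numeric(signature)) signature <- genes[signature]
  if (!is.null(signature) && !all(signature %in% genes)) {
    stop("signature contains ids outside the gene universe")
  }
  high <- samples[seq_len(n_high)]
  m <- with_seed(seed, {
    base <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1)
    mu <- matrix(base, n_genes, n_samples)
    if (!is.null(signature) && n_high > 0) {
      mu[genes %in% signature, seq_len(n_high)] <-
        mu[genes %in% signature, seq_len(n_high)] * 2^shift
    }
    matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
           n_genes, n_samples)
  })
  dimnames(m) <- list(genes, samples)
  list(counts = m, high_samples = high)
}
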