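# Codon content analysis (CCA): per-gene codon and amino-acid content from
# CDS sequences, the transcriptome-wide top-quartile membership background,
# and chi-squared enrichment of gene sets against that background.

#' Validate a table of CDS records
#'
#' @param records data.frame with columns `gene_id`, `transcript_id`,
#'   `sequence`.
#' @return The records, invisibly, after validation.
#' @keywords internal
validate_cds <- function(records) {
  need <- c("gene_id", "transcript_id", "sequence")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data.frame with columns gene_id, transcript_id, sequence")
  }
  len <- nchar(records$sequence)
  bad <- which(len %% 3 != 0)
  if (length(bad)) {
    stop(sprintf(
      "CDS length not divisible by 3 for: %s",
      paste(records$transcript_id[bad], collapse = ", ")
    ))
  }
  invisible(records)
}

#' Keep the longest transcript per gene
#'
#' Content analysis uses one representative CDS per gene: the longest
#' transcript, with ties broken by transcript id (lexicographic, ascending)
#' so the choice is deterministic.
#'
#' @param records data.frame of CDS records (`gene_id`, `transcript_id`,
#'   `sequence`), possibly several transcripts per gene.
#' @return One row per gene, ordered by `gene_id`.
#' @export
select_longest_transcript <- function(records) {
  validate_cds(records)
  records <- records[order(-nchar(records$sequence), records$transcript_id), ]
  out <- records[!duplicated(records$gene_id), ]
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Count in-frame codons of one CDS
#'
#' Counts non-overlapping frame-0 triplets. Triplets containing characters
#' outside ACGT (ambiguity codes such as N) are skipped; the number skipped
#' is attached as attribute `skipped`.
#'
#' @param sequence A DNA string with length divisible by 3.
#' @return Named integer vector over the 64 codons, with attribute
#'   `skipped`.
#' @export
#' @examples
#' count_codons("ATGGTGGTGGTTTAA")
count_codons <- function(sequence) {
  if (length(sequence) != 1) stop("count_codons takes a single sequence")
  if (nchar(sequence) %% 3 != 0) {
    stop("sequence length not divisible by 3")
  }
  counts <- Biostrings::trinucleotideFrequency(
    Biostrings::DNAString(sequence), step = 3
  )
  structure(counts, skipped = as.integer(nchar(sequence) / 3 - sum(counts)))
}

# gene x 64 codon count matrix for a whole record table (one row per gene)
codon_count_matrix <- function(records) {
  validate_cds(records)
  dss <- Biostrings::DNAStringSet(records$sequence)
  m <- Biostrings::trinucleotideFrequency(dss, step = 3)
  rownames(m) <- records$gene_id
  m
}

#' Per-gene codon or amino-acid content fractions
#'
#' Content of a feature is its count divided by the number of sense codons
#' in the CDS: stop codons are excluded from both numerator alphabet and
#' denominator, the start codon is included. At amino-acid level, synonymous
#' codon fractions are summed, so fractions sum to 1 at either level.
#' Codons containing ambiguous bases are skipped; records in which more than
#' `max_skip_frac` of codons were skipped are dropped with a warning, as are
#' records with no sense codons.
#'
#' @param records data.frame of CDS records, one transcript per gene (see
#'   [select_longest_transcript()]).
#' @param level `"codon"` (61 features) or `"amino_acid"` (20 features).
#' @param max_skip_frac Maximum tolerated fraction of skipped codons per
#'   record (default 0.05).
#' @return Numeric matrix, genes x features, with attribute `denominator`
#'   (sense-codon count per gene).
#' @export
content_profiles <- function(records, level = c("codon", "amino_acid"),
                             max_skip_frac = 0.05) {
  level <- match.arg(level)
  cnt <- codon_count_matrix(records)
  total <- nchar(records$sequence) / 3
  skipped <- total - rowSums(cnt)
  drop <- total > 0 & skipped / pmax(total, 1) > max_skip_frac
  sense <- cnt[, SENSE_CODONS, drop = FALSE]
  denom <- rowSums(sense)
  drop <- drop | denom == 0
  if (any(drop)) {
    warning(sprintf("%d record(s) dropped (ambiguous or empty CDS): %s",
                    sum(drop), paste(rownames(cnt)[drop], collapse = ", ")))
    sense <- sense[!drop, , drop = FALSE]
    denom <- denom[!drop]
  }
  if (!nrow(sense)) stop("no usable records")
  frac <- sense / denom
  if (level == "amino_acid") {
    ind <- outer(CODON_AA, AMINO_ACIDS, "==") * 1
    rownames(ind) <- SENSE_CODONS
    colnames(ind) <- AMINO_ACIDS
    frac <- frac %*% ind
  }
  structure(frac, denominator = denom)
}

#' Build the transcriptome content background
#'
#' For each feature (codon or amino acid), the background records which
#' genes fall in the top `top_frac` of that feature's content distribution
#' across the transcriptome. Membership is rank-based: exactly
#' `ceiling(top_frac * N)` genes per feature, ties broken by gene id, so the
#' top-25% rule is exact under ties.
#'
#' @param content Gene x feature content matrix from [content_profiles()].
#' @param top_frac Membership fraction, default 0.25.
#' @return An object of class `codon_background`: list with `content`,
#'   logical membership matrix `members`, `k` (members per feature), `n`
#'   (universe size), `level` and `top_frac`.
#' @export
build_background <- function(content, top_frac = 0.25) {
  if (is.null(dim(content)) || nrow(content) < 4) {
    stop("background requires a content matrix with at least 4 genes")
  }
  n <- nrow(content)
  k <- ceiling(top_frac * n)
  ids <- rownames(content)
  members <- matrix(FALSE, n, ncol(content), dimnames = dimnames(content))
  for (j in seq_len(ncol(content))) {
    ord <- order(-content[, j], ids)
    members[ord[seq_len(k)], j] <- TRUE
  }
  structure(
    list(content = content, members = members, k = k, n = n,
         level = if (ncol(content) == length(AMINO_ACIDS)) "amino_acid" else "codon",
         top_frac = top_frac),
    class = "codon_background"
  )
}

#' @export
print.codon_background <- function(x, ...) {
  cat(sprintf(
    "codon_background: %d genes x %d %s features; top %.0f%% membership (k = %d)\n",
    x$n, ncol(x$content), x$level, 100 * x$top_frac, x$k
  ))
  invisible(x)
}

#' Feature members of a background
#'
#' @param background A `codon_background`.
#' @param feature A codon or amino acid present in the background.
#' @return Character vector of member gene ids.
#' @export
background_members <- function(background, feature) {
  stopifnot(inherits(background, "codon_background"))
  if (!feature %in% colnames(background$members)) {
    stop(sprintf("feature '%s' not in background", feature))
  }
  rownames(background$members)[background$members[, feature]]
}

#' Codon / amino-acid enrichment of a gene set
#'
#' For each feature, genes are cross-classified as in-set vs out-of-set and
#' top-quartile member vs non-member, and the 2x2 table is tested with the
#' Pearson chi-squared statistic (1 df, no continuity correction). Direction
#' is `enriched` when the in-set member fraction exceeds the out-of-set
#' fraction and the test is significant at `alpha`, `impoverished` for the
#' reverse, `none` otherwise. Raw p-values drive the direction call;
#' Benjamini-Hochberg adjusted values are reported alongside. Rows whose
#' smallest expected cell count is below 1 are flagged `low_expected`.
#'
#' @param gene_set Character vector of gene ids; must be a subset of the
#'   background universe.
#' @param background A `codon_background` from [build_background()].
#' @param alpha Significance level for the direction call (default 0.05).
#' @return data.frame with columns `feature`, `k_set`, `n_set`, `k_bg`,
#'   `n_bg`, `chi2`, `p`, `p_adj`, `direction`, `significant`,
#'   `low_expected`.
#' @export
enrichment_test <- function(gene_set, background, alpha = 0.05) {
  stopifnot(inherits(background, "codon_background"))
  universe <- rownames(background$members)
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("gene_set is empty")
  missing <- setdiff(gene_set, universe)
  if (length(missing)) {
    stop(sprintf("gene_set contains ids outside the background universe: %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  in_set <- universe %in% gene_set
  n_set <- sum(in_set)
  n_bg <- length(universe) - n_set
  if (n_bg == 0) stop("gene_set equals the whole universe")
  k_set <- colSums(background$members[in_set, , drop = FALSE])
  k_bg <- colSums(background$members) - k_set
  ct <- chisq_2x2(k_set, n_set - k_set, k_bg, n_bg - k_bg)
  significant <- ct$p < alpha
  direction <- rep("none", length(k_set))
  delta <- k_set / n_set - k_bg / n_bg
  direction[significant & delta > 0] <- "enriched"
  direction[significant & delta < 0] <- "impoverished"
  data.frame(
    feature = colnames(background$members),
    k_set = unname(k_set), n_set = n_set,
    k_bg = unname(k_bg), n_bg = n_bg,
    chi2 = ct$chi2, p = ct$p,
    p_adj = stats::p.adjust(ct$p, method = "BH"),
    direction = direction,
    significant = significant,
    low_expected = ct$min_expected < 1,
    row.names = NULL
  )
}
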