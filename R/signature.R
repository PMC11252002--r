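# Translational-signature derivation and scoring: the protein/mRNA
# threshold classifier, intersection with amino-acid content membership,
# chi-squared superposition with translation-level calls, count filtering
# and log-CPM, ssGSEA sample scoring, extreme-group selection, and the
# relative nuclear-fragmentation score used by the re-sensitisation screen.

#' Classify genes by paired protein and mRNA fold changes
#'
#' A gene is called `translation_down` when its protein log2 fold change is
#' below `-protein_cut` while its mRNA log2 fold change stays inside
#' `(-rna_cut, rna_cut)` — a protein-level drop not explained by mRNA.
#' `translation_up` is the mirror rule. Genes whose mRNA moves beyond
#' `rna_cut` in the same direction as a beyond-threshold protein change are
#' `concordant` (mRNA-driven); everything else is `unclassified`. Genes
#' with missing values are dropped with a message.
#'
#' @param pairs data.frame (`gene_id`, `protein_log2fc`, `rna_log2fc`).
#' @param protein_cut Protein threshold, default 0.32.
#' @param rna_cut mRNA window half-width, default 1.
#' @return `pairs` with a `group` column.
#' @export
#' @examples
#' classify_translation_groups(
#'   data.frame(gene_id = "a", protein_log2fc = -0.5, rna_log2fc = 0.2)
#' )
classify_translation_groups <- function(pairs, protein_cut = 0.32,
                                        rna_cut = 1.0) {
  stopifnot(all(c("gene_id", "protein_log2fc", "rna_log2fc") %in% names(pairs)))
  drop <- is.na(pairs$protein_log2fc) | is.na(pairs$rna_log2fc)
  if (any(drop)) {
    message(sprintf("%d gene(s) with missing fold changes dropped", sum(drop)))
    pairs <- pairs[!drop, ]
  }
  rna_flat <- abs(pairs$rna_log2fc) < rna_cut
  group <- rep("unclassified", nrow(pairs))
  group[rna_flat & pairs$protein_log2fc < -protein_cut] <- "translation_down"
  group[rna_flat & pairs$protein_log2fc > protein_cut] <- "translation_up"
  group[!rna_flat & abs(pairs$protein_log2fc) > protein_cut &
          sign(pairs$rna_log2fc) == sign(pairs$protein_log2fc)] <- "concordant"
  pairs$group <- group
  rownames(pairs) <- NULL
  pairs
}

#' Derive the translational signature
#'
#' The signature is the intersection of the `translation_down` genes (from
#' [classify_translation_groups()]) with the members of one amino acid's
#' top content quartile — genes losing protein without losing mRNA that
#' are rich in the amino acid of interest.
#'
#' @param pairs Classified pairs (with a `group` column).
#' @param content_members Character vector of content-member gene ids,
#'   e.g. `background_members(bg_aa, "Val")`.
#' @return Object of class `translation_signature`: list with `genes` and
#'   a `provenance` record (thresholds and member-set size).
#' @export
derive_signature <- function(pairs, content_members) {
  if (!"group" %in% names(pairs)) {
    stop("pairs must be classified first (classify_translation_groups)")
  }
  down <- pairs$gene_id[pairs$group == "translation_down"]
  genes <- sort(intersect(down, content_members))
  if (!length(genes)) warning("signature is empty")
  structure(
    list(genes = genes,
         provenance = list(n_translation_down = length(down),
                           n_content_members = length(content_members),
                           n_signature = length(genes))),
    class = "translation_signature"
  )
}

#' @export
print.translation_signature <- function(x, ...) {
  cat(sprintf(
    "translation_signature: %d genes (%d translation-down, %d content members)\n",
    length(x$genes), x$provenance$n_translation_down,
    x$provenance$n_content_members
  ))
  invisible(x)
}

#' Superposition of the signature with translation-level calls
#'
#' Cross-classifies a gene universe by signature membership and by a
#' translational call (significant change in the requested direction in a
#' ribosome- or polysome-profiling differential table) and tests the 2x2
#' table with the Pearson chi-squared statistic.
#'
#' @param signature A `translation_signature` or character vector of genes.
#' @param calls Differential table (`gene_id`, `log2fc`, `significant`).
#' @param direction `"down"` (default) or `"up"`: which translational call
#'   to superpose.
#' @return List with `contingency` (2x2 matrix), `chi2`, `p` and
#'   `degenerate` flag.
#' @export
superposition_test <- function(signature, calls, direction = c("down", "up")) {
  direction <- match.arg(direction)
  genes <- if (inherits(signature, "translation_signature")) {
    signature$genes
  } else {
    signature
  }
  in_sig <- calls$gene_id %in% genes
  called <- calls$significant &
    (if (direction == "down") calls$log2fc < 0 else calls$log2fc > 0)
  a <- sum(in_sig & called); b <- sum(in_sig & !called)
  c <- sum(!in_sig & called); d <- sum(!in_sig & !called)
  ct <- chisq_2x2(a, b, c, d)
  contingency <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                        dimnames = list(c("signature", "other"),
                                        c(paste0("called_", direction),
                                          "not_called")))
  list(contingency = contingency, chi2 = ct$chi2, p = ct$p,
       degenerate = ct$degenerate)
}

#' Filter genes with low counts in both groups
#'
#' A gene is removed when the fraction of its samples with fewer than
#' `min_count` counts exceeds `max_frac` in group 1 AND in group 2.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Named vector (sample -> group label, two levels).
#' @param min_count Count threshold (default 10).
#' @param max_frac Maximum tolerated low-count sample fraction per group
#'   (default 0.30).
#' @return The filtered matrix.
#' @export
filter_low_counts <- function(counts, groups, min_count = 10,
                              max_frac = 0.30) {
  groups <- groups[colnames(counts)]
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  low <- counts < min_count
  f1 <- rowMeans(low[, groups == lv[1], drop = FALSE])
  f2 <- rowMeans(low[, groups == lv[2], drop = FALSE])
  counts[!(f1 > max_frac & f2 > max_frac), , drop = FALSE]
}

#' Log counts-per-million transform
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)` per sample, the
#' standard moderated log-CPM.
#'
#' @param counts Gene x sample count matrix.
#' @return Transformed matrix of the same shape.
#' @export
log_cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library sizes must be positive")
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' Per sample, genes are ranked by expression (descending; ties get
#' average ranks) and the score is the sum, down the ranked list, of the
#' difference between the weighted in-signature empirical CDF (gene weight
#' = rank^`exponent`) and the unweighted out-of-signature ECDF. Scores are
#' then linearly rescaled across samples by their range (max - min), the
#' usual cross-sample normalisation. Being rank-based, a sample's score is
#' invariant to any strictly monotone transform of its expression values.
#'
#' @param expression Gene x sample numeric matrix (e.g. log-CPM).
#' @param signature A `translation_signature` or character vector of genes;
#'   at least one must be present in the matrix.
#' @param exponent Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the cross-sample score range (default `TRUE`).
#' @return data.frame (`sample_id`, `score`, `flagged` — degenerate
#'   constant-expression samples score 0).
#' @export
ssgsea_score <- function(expression, signature, exponent = 0.25,
                         normalize = TRUE) {
  genes <- if (inherits(signature, "translation_signature")) {
    signature$genes
  } else {
    signature
  }
  in_sig <- rownames(expression) %in% genes
  if (!any(in_sig)) stop("no signature gene present in the expression matrix")
  if (all(in_sig)) stop("signature covers the whole gene universe")
  scores <- numeric(ncol(expression))
  flagged <- logical(ncol(expression))
  for (j in seq_len(ncol(expression))) {
    x <- expression[, j]
    if (stats::sd(x) == 0) {
      flagged[j] <- TRUE
      next
    }
    r <- rank(x, ties.method = "average") # top gene has rank N
    ord <- order(x, decreasing = TRUE)
    sig_ord <- in_sig[ord]
    w <- r[ord]^exponent
    cdf_in <- cumsum(w * sig_ord) / sum(w * sig_ord)
    cdf_out <- cumsum(!sig_ord) / sum(!sig_ord)
    scores[j] <- sum(cdf_in - cdf_out)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  data.frame(sample_id = colnames(expression), score = scores,
             flagged = flagged, row.names = NULL)
}

#' Label the highest- and lowest-scoring samples
#'
#' `k = round-half-up(frac * N)` samples with the highest scores are
#' labelled `high`, the `k` lowest `low`, the rest `middle`. Ties are
#' broken by sample id. `2k == N` (empty middle) is allowed; `2k > N` is
#' an error.
#'
#' @param scores data.frame (`sample_id`, `score`).
#' @param frac Extreme fraction per tail (default 0.15).
#' @return `scores` with a `group` column.
#' @export
#' @examples
#' # 233 samples at 15% per tail -> groups of 35
group_extremes <- function(scores, frac = 0.15) {
  n <- nrow(scores)
  k <- floor(frac * n + 0.5) # round half up
  if (k < 1) stop("extreme groups are empty at this fraction")
  if (2 * k > n) stop("extreme groups would overlap (2k > N)")
  ord_hi <- order(-scores$score, scores$sample_id)
  ord_lo <- order(scores$score, scores$sample_id)
  group <- rep("middle", n)
  group[ord_hi[seq_len(k)]] <- "high"
  group[ord_lo[seq_len(k)]] <- "low"
  scores$group <- group
  scores
}

#' Relative nuclear fragmentation score
#'
#' Drug-induced cell death normalised for spontaneous background:
#' `1 + 100 * (induced - spontaneous) / (100 - spontaneous)`. Equal
#' induced and spontaneous fragmentation gives 1 (no drug effect); values
#' below 1 indicate less death under treatment than baseline.
#'
#' @param induced_pct,spontaneous_pct Percentages in `[0, 100)`.
#' @return Numeric score (vectorised).
#' @export
#' @examples
#' relative_fragmentation(45, 20) # 32.25
relative_fragmentation <- function(induced_pct, spontaneous_pct) {
  if (any(induced_pct < 0 | induced_pct >= 100) ||
      any(spontaneous_pct < 0 | spontaneous_pct >= 100)) {
    stop("percentages must lie in [0, 100)")
  }
  1 + 100 * (induced_pct - spontaneous_pct) / (100 - spontaneous_pct)
}
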