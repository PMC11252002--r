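# tRNA quantification: isodecoder count tables are aggregated to
# isoacceptor (same anticodon) and alloisoacceptor (same amino acid)
# levels, tested for differential expression between conditions, and
# overlaid with codon/amino-acid enrichment calls for concordance.

# sample columns of an isodecoder count table
trna_sample_cols <- function(counts, conditions) {
  samples <- names(conditions)
  missing <- setdiff(samples, names(counts))
  if (length(missing)) {
    stop(sprintf("samples missing from the count table: %s",
                 paste(missing, collapse = ", ")))
  }
  samples
}

#' Aggregate isodecoder counts to isoacceptor or alloisoacceptor level
#'
#' Isoacceptors sum all isodecoder gene counts sharing one anticodon (and
#' amino acid); alloisoacceptors sum all isodecoders charging one amino
#' acid. With `significant_only = TRUE` (an isoacceptor-level option), only
#' isodecoders that individually pass a two-sided t-test between conditions
#' at `alpha` contribute; keys in which no isodecoder passes are emitted
#' with zero counts and `n_contributing = 0`.
#'
#' @param counts Isodecoder data.frame (`isodecoder_id`, `amino_acid`,
#'   `anticodon`, one column per sample).
#' @param conditions Named vector (sample -> `SENS`/`RES`).
#' @param level `"isoacceptor"` or `"alloisoacceptor"`.
#' @param significant_only Filter isodecoders on their own differential
#'   significance before summing (default `FALSE`).
#' @param alpha Level of the per-isodecoder filter test.
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return data.frame keyed by `amino_acid` (+ `anticodon` at isoacceptor
#'   level) with per-sample sums and `n_contributing`.
#' @export
aggregate_trna <- function(counts, conditions,
                           level = c("isoacceptor", "alloisoacceptor"),
                           significant_only = FALSE, alpha = 0.05,
                           var_equal = TRUE) {
  level <- match.arg(level)
  if (!nrow(counts)) stop("empty isodecoder table")
  samples <- trna_sample_cols(counts, conditions)
  aa_per_ac <- tapply(counts$amino_acid, counts$anticodon,
                      function(x) length(unique(x)))
  if (any(aa_per_ac > 1)) {
    stop(sprintf("anticodon(s) mapped to several amino acids: %s",
                 paste(names(aa_per_ac)[aa_per_ac > 1], collapse = ", ")))
  }
  use <- rep(TRUE, nrow(counts))
  if (significant_only) {
    sens <- samples[conditions[samples] == "SENS"]
    res <- samples[conditions[samples] == "RES"]
    p <- vapply(seq_len(nrow(counts)), function(i) {
      safe_t_test(as.numeric(counts[i, res]), as.numeric(counts[i, sens]),
                  var_equal = var_equal)$p
    }, numeric(1))
    use <- p < alpha
  }
  key <- if (level == "isoacceptor") {
    paste(counts$amino_acid, counts$anticodon, sep = "-")
  } else {
    counts$amino_acid
  }
  all_keys <- unique(key)
  mat <- as.matrix(counts[samples])
  sums <- rowsum(mat * use, group = key)[all_keys, , drop = FALSE]
  contributing <- rowsum(as.numeric(use), group = key)[all_keys, ]
  out <- data.frame(amino_acid = counts$amino_acid[match(all_keys, key)])
  if (level == "isoacceptor") {
    out$anticodon <- counts$anticodon[match(all_keys, key)]
  }
  out[samples] <- sums
  out$n_contributing <- as.integer(contributing)
  rownames(out) <- NULL
  out
}

#' Differential expression of aggregated tRNA levels
#'
#' Two-sided unpaired t-test (pooled variance by default) of RES vs SENS
#' per-sample sums, with `log2fc = log2((mean(RES) + pseudo) /
#' (mean(SENS) + pseudo))`. Direction is `up`/`down` for significant rows
#' by fold-change sign, `none` otherwise.
#'
#' @param agg Aggregated table from [aggregate_trna()].
#' @param conditions Named vector (sample -> `SENS`/`RES`), >= 2 replicates
#'   per condition.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @param pseudo Pseudo-count added to the group means (default 0.5).
#' @return `agg` with columns `log2fc`, `t_stat`, `p`, `direction` added.
#' @export
trna_differential <- function(agg, conditions, alpha = 0.05,
                              var_equal = TRUE, pseudo = 0.5) {
  samples <- trna_sample_cols(agg, conditions)
  sens <- samples[conditions[samples] == "SENS"]
  res <- samples[conditions[samples] == "RES"]
  if (length(sens) < 2 || length(res) < 2) {
    stop("need >= 2 replicates per condition")
  }
  stats_rows <- lapply(seq_len(nrow(agg)), function(i) {
    x <- as.numeric(agg[i, res])
    y <- as.numeric(agg[i, sens])
    tt <- safe_t_test(x, y, var_equal = var_equal)
    data.frame(log2fc = log2((mean(x) + pseudo) / (mean(y) + pseudo)),
               t_stat = tt$t, p = tt$p)
  })
  out <- cbind(agg, do.call(rbind, stats_rows))
  out$direction <- ifelse(out$p < alpha,
                          ifelse(out$log2fc > 0, "up", "down"), "none")
  out
}

#' Concordance of content enrichment with tRNA regulation
#'
#' Overlays an enrichment table (amino-acid or codon level) with a
#' differential tRNA table. At amino-acid level, features pair with
#' alloisoacceptors by amino acid; at codon level, with isoacceptors whose
#' anticodon is the exact reverse complement of the codon. One row is
#' emitted per feature significant in either input; a feature with no
#' cognate tRNA row gets `trna_direction = "absent"`. A row is concordant
#' when both calls are significant and point the same way (enriched with
#' up, impoverished with down).
#'
#' @param enrichment Output of [enrichment_test()].
#' @param trna Output of [trna_differential()].
#' @return data.frame (`feature`, `enrichment_direction`, `trna_direction`,
#'   `concordant`).
#' @export
trna_concordance <- function(enrichment, trna) {
  codon_level <- any(enrichment$feature %in% SENSE_CODONS)
  if (codon_level) {
    if (!"anticodon" %in% names(trna)) {
      stop("codon-level concordance needs an isoacceptor-level tRNA table")
    }
    idx <- match(codon_to_anticodon(enrichment$feature), trna$anticodon)
  } else {
    idx <- match(enrichment$feature, trna$amino_acid)
  }
  trna_dir <- ifelse(is.na(idx), "absent", trna$direction[idx])
  keep <- enrichment$direction != "none" | trna_dir %in% c("up", "down")
  out <- data.frame(
    feature = enrichment$feature,
    enrichment_direction = enrichment$direction,
    trna_direction = trna_dir,
    concordant = (enrichment$direction == "enriched" & trna_dir == "up") |
      (enrichment$direction == "impoverished" & trna_dir == "down")
  )[keep, ]
  rownames(out) <- NULL
  out
}
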