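# End-to-end orchestration and file formats. Readers and writers round-trip
# every typed table the stages exchange (multi-FASTA for CDS, headered TSV
# for tables); run_pipeline() chains the stages on synthetic inputs and
# writes a reproducibility report (config snapshot, input hashes, output
# summaries) next to the outputs. Coordinates are 0-based half-open
# internally; TSV is tab-only with a header row; CRLF input is accepted.

#' Write CDS records as multi-FASTA
#'
#' Headers are `gene_id|transcript_id` (delimiter configurable); sequences
#' wrapped at 60 columns.
#'
#' @param records CDS records data.frame.
#' @param path Output path.
#' @param delim Header delimiter (default `"|"`).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path, delim = "|") {
  dss <- Biostrings::DNAStringSet(records$sequence)
  names(dss) <- paste(records$gene_id, records$transcript_id, sep = delim)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Read CDS records from multi-FASTA
#'
#' @param path FASTA path; headers parsed as `gene_id<delim>transcript_id`
#'   (a header without the delimiter is used for both ids).
#' @param delim Header delimiter (default `"|"`).
#' @return CDS records data.frame (`gene_id`, `transcript_id`, `sequence`).
#' @export
read_cds_fasta <- function(path, delim = "|") {
  dss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(dss), delim, fixed = TRUE)
  data.frame(
    gene_id = vapply(parts, `[`, "", 1),
    transcript_id = vapply(parts, function(p) p[min(2, length(p))], ""),
    sequence = as.character(dss),
    row.names = NULL
  )
}

#' Write a data.frame as headered TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV, checking required columns
#'
#' @param path Input path (LF or CRLF line endings).
#' @param required Character vector of columns that must be present.
#' @return data.frame.
#' @export
read_tsv <- function(path, required = NULL) {
  x <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop(sprintf("%s: missing required column(s): %s",
                   path, paste(missing, collapse = ", ")))
    }
  }
  x
}

#' Default pipeline configuration
#'
#' All tunables with their defaults: simulation sizes and planted effects,
#' the top-quartile fraction, test level, site offsets, the translation
#' classifier thresholds, count-filter and scoring parameters. Any element
#' can be overridden through `run_pipeline(config = list(...))`.
#'
#' @param out_dir Output directory.
#' @param seed Top-level seed; stage seeds are derived from it.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("codonreprog_run_"),
                           seed = 42L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = c("simulate", "background", "enrichment", "trna", "ribo",
               "signature", "score"),
    n_genes = 600L,
    cds_length_range = c(100L, 400L),
    planted = list(name = "biased", fraction = 0.1, codon = "GTG",
                   multiplier = 4),
    alpha = 0.05,
    top_frac = 0.25,
    offsets = c(E = 9L, P = 12L, A = 15L),
    pause = list(codon = "GTG", offset = 15L, fold = 4),
    read_length = 30L,
    reads_per_transcript = 150L,
    trna_planted = list(list(amino_acid = "Val", anticodon = "CAC", fold = 2)),
    trna_replicates = 3L,
    fc_amino_acid = "Val",
    fc_mean_shift = -0.5,
    fc_noise_sd = 0.3,
    sig_protein_shift = -1,
    sig_noise_sd = 0.1,
    protein_cut = 0.32,
    rna_cut = 1.0,
    n_samples = 60L,
    n_high_samples = 9L,
    expr_shift = 1,
    ssgsea_exponent = 0.25,
    extreme_frac = 0.15,
    min_count = 10,
    max_low_frac = 0.30
  ), class = "run_config")
}

stage_seed <- function(config, stage) {
  # fixed per-stage offsets keep stages reproducible independently
  offsets <- c(simulate = 1L, trna = 2L, ribo = 3L, fc = 4L, sig = 5L,
               expr = 6L)
  (config$seed * 131L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order: simulate the
#' transcriptome and all omic layers, build codon and amino-acid
#' backgrounds, test the planted gene set for enrichment, aggregate and
#' test tRNA counts with concordance overlays, compute ribosome-footprint
#' occupancy/metagene/stratified statistics, derive the translational
#' signature with its superposition test, and score an expression cohort
#' with extreme-group labels. Stage outputs are written as TSV (plus the
#' transcriptome FASTA) under `config$out_dir`, together with
#' `config.yaml` and `report.yaml`. Reruns with the same config are
#' byte-identical.
#'
#' @param config List of overrides merged into [default_config()], or a
#'   full `run_config`.
#' @return The run report (list of per-stage summaries), invisibly;
#'   also written as `report.yaml`.
#' @export
run_pipeline <- function(config = list()) {
  base <- default_config()
  if (!inherits(config, "run_config")) {
    unknown <- setdiff(names(config), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown config field(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    base[names(config)] <- config
    config <- base
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  on <- function(stage) stage %in% config$stages
  report <- list(config = config[setdiff(names(config), "stages")],
                 stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }
  path <- function(name) file.path(config$out_dir, name)

  records <- NULL
  if (on("simulate")) {
    records <- simulate_transcriptome(
      n_genes = config$n_genes,
      cds_length_range = config$cds_length_range,
      planted_sets = list(config$planted),
      seed = stage_seed(config, "simulate")
    )
    write_cds_fasta(records, path("transcriptome.fasta"))
    write_tsv(records[c("gene_id", "transcript_id", "planted_set")],
              path("planted_sets.tsv"))
    note("simulate", n_genes = nrow(records),
         n_planted = sum(!is.na(records$planted_set)),
         fasta = "transcriptome.fasta",
         fasta_md5 = unname(tools::md5sum(path("transcriptome.fasta"))))
  } else {
    fasta <- path("transcriptome.fasta")
    if (!file.exists(fasta)) stop("no transcriptome: enable 'simulate' or provide transcriptome.fasta")
    records <- read_cds_fasta(fasta)
  }

  bg_codon <- bg_aa <- NULL
  if (on("background") || on("enrichment") || on("ribo") || on("signature")) {
    bg_codon <- build_background(content_profiles(records, "codon"),
                                 top_frac = config$top_frac)
    bg_aa <- build_background(content_profiles(records, "amino_acid"),
                              top_frac = config$top_frac)
    note("background", n_genes = bg_codon$n, k = bg_codon$k)
  }

  if (on("enrichment")) {
    planted_genes <- records$gene_id[!is.na(records$planted_set)]
    enr_codon <- enrichment_test(planted_genes, bg_codon, alpha = config$alpha)
    enr_aa <- enrichment_test(planted_genes, bg_aa, alpha = config$alpha)
    write_tsv(enr_codon, path("enrichment_codon.tsv"))
    write_tsv(enr_aa, path("enrichment_aa.tsv"))
    note("enrichment",
         n_set = length(planted_genes),
         significant_codons = sum(enr_codon$significant),
         significant_aas = sum(enr_aa$significant))
  }

  if (on("trna")) {
    sim <- simulate_trna_counts(planted = config$trna_planted,
                                replicates = config$trna_replicates,
                                seed = stage_seed(config, "trna"))
    iso <- trna_differential(
      aggregate_trna(sim$counts, sim$conditions, "isoacceptor"),
      sim$conditions, alpha = config$alpha)
    allo <- trna_differential(
      aggregate_trna(sim$counts, sim$conditions, "alloisoacceptor"),
      sim$conditions, alpha = config$alpha)
    write_tsv(iso, path("trna_isoacceptor.tsv"))
    write_tsv(allo, path("trna_alloisoacceptor.tsv"))
    if (on("enrichment")) {
      enr_codon <- read_tsv(path("enrichment_codon.tsv"))
      conc <- trna_concordance(enr_codon, iso)
      write_tsv(conc, path("trna_concordance.tsv"))
      note("trna", n_isoacceptors = nrow(iso),
           n_up = sum(iso$direction == "up"),
           n_concordant = sum(conc$concordant))
    } else {
      note("trna", n_isoacceptors = nrow(iso),
           n_up = sum(iso$direction == "up"))
    }
  }

  if (on("ribo")) {
    rpf_null <- simulate_rpf_dataset(
      records, read_length = config$read_length,
      reads_per_transcript = config$reads_per_transcript,
      seed = stage_seed(config, "ribo"))
    rpf_pause <- simulate_rpf_dataset(
      records, pause_codon = config$pause$codon,
      pause_offset = config$pause$offset,
      fold_enrichment = config$pause$fold,
      read_length = config$read_length,
      reads_per_transcript = config$reads_per_transcript,
      seed = stage_seed(config, "ribo") + 1L)
    occ <- codon_occupancy(rpf_pause, rpf_null, records,
                           offsets = config$offsets)
    meta <- metagene_profile(rpf_null, cds_annotation(records))
    fc <- simulate_fc_table(records, amino_acid = config$fc_amino_acid,
                            mean_shift = config$fc_mean_shift,
                            noise_sd = config$fc_noise_sd,
                            seed = stage_seed(config, "fc"))
    strat <- stratify_fc(fc, bg_aa$content, config$fc_amino_acid)
    write_tsv(occ, path("codon_occupancy.tsv"))
    write_tsv(as.data.frame(meta), path("metagene.tsv"))
    write_tsv(fc, path("ribo_fc_table.tsv"))
    top_site <- occ[occ$offset == config$pause$offset, ]
    note("ribo",
         n_reads = sum(rpf_null$count),
         max_shift_codon = top_site$codon[which.max(abs(top_site$z_shift))],
         stratified_p = strat$p)
  }

  signature <- NULL
  if (on("signature")) {
    ss <- stage_seed(config, "sig")
    planted_genes <- records$gene_id[!is.na(records$planted_set)]
    n <- nrow(records)
    in_planted <- records$gene_id %in% planted_genes
    fcs <- with_seed(ss, {
      data.frame(
        gene_id = records$gene_id,
        protein_log2fc = stats::rnorm(
          n, ifelse(in_planted, config$sig_protein_shift, 0),
          config$sig_noise_sd),
        rna_log2fc = stats::rnorm(n, 0, config$sig_noise_sd)
      )
    })
    pairs <- classify_translation_groups(fcs, protein_cut = config$protein_cut,
                                         rna_cut = config$rna_cut)
    signature <- derive_signature(pairs, background_members(bg_aa, "Val"))
    ribo_calls <- data.frame(
      gene_id = records$gene_id,
      log2fc = fcs$protein_log2fc,
      significant = abs(fcs$protein_log2fc) > config$protein_cut
    )
    sup <- superposition_test(signature, ribo_calls, direction = "down")
    write_tsv(pairs, path("translation_groups.tsv"))
    writeLines(signature$genes, path("signature_genes.txt"))
    note("signature",
         n_translation_down = signature$provenance$n_translation_down,
         n_signature = length(signature$genes),
         superposition_chi2 = sup$chi2, superposition_p = sup$p)
  }

  if (on("score")) {
    if (is.null(signature) || !length(signature$genes)) {
      stop("scoring requires a non-empty signature stage")
    }
    sim <- simulate_expression_matrix(
      n_genes = config$n_genes, n_samples = config$n_samples,
      signature = signature$genes, n_high = config$n_high_samples,
      shift = config$expr_shift, seed = stage_seed(config, "expr"))
    groups <- stats::setNames(
      ifelse(colnames(sim$counts) %in% sim$high_samples, "high", "other"),
      colnames(sim$counts))
    filtered <- filter_low_counts(sim$counts, groups,
                                  min_count = config$min_count,
                                  max_frac = config$max_low_frac)
    expr <- log_cpm(filtered)
    scores <- ssgsea_score(expr, signature,
                           exponent = config$ssgsea_exponent)
    scores <- group_extremes(scores, frac = config$extreme_frac)
    write_tsv(scores, path("sample_scores.tsv"))
    note("score", n_samples = ncol(expr),
         n_genes_after_filter = nrow(expr),
         n_high = sum(scores$group == "high"),
         n_low = sum(scores$group == "low"))
  }

  cfg_out <- report$config
  cfg_out$offsets <- as.list(cfg_out$offsets)
  yaml::write_yaml(cfg_out, path("config.yaml"))
  yaml::write_yaml(report$stages, path("report.yaml"))
  invisible(report)
}
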