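test_that("translation groups follow the threshold rules", {
  pairs <- data.frame(
    gene_id = c("down", "mrna_driven", "up", "flat", "edge"),
    protein_log2fc = c(-0.5, -0.5, 0.4, 0.1, -0.32),
    rna_log2fc = c(0.2, -1.5, 0.0, 0.0, 0.0)
  )
  out <- classify_translation_groups(pairs)
  expect_equal(out$group[out$gene_id == "down"], "translation_down")
  expect_equal(out$group[out$gene_id == "mrna_driven"], "concordant")
  expect_equal(out$group[out$gene_id == "up"], "translation_up")
  expect_equal(out$group[out$gene_id == "flat"], "unclassified")
  expect_equal(out$group[out$gene_id == "edge"], "unclassified") # strict cut

  with_na <- rbind(pairs, data.frame(gene_id = "na", protein_log2fc = NA,
                                     rna_log2fc = 0))
  expect_message(out2 <- classify_translation_groups(with_na), "dropped")
  expect_equal(nrow(out2), 5)
})

test_that("classifier agrees with brute-force set logic", {
  set.seed(41)
  pairs <- data.frame(gene_id = sprintf("g%03d", 1:500),
                      protein_log2fc = rnorm(500, 0, 0.6),
                      rna_log2fc = rnorm(500, 0, 0.8))
  out <- classify_translation_groups(pairs)
  down <- pairs$gene_id[abs(pairs$rna_log2fc) < 1 & pairs$protein_log2fc < -0.32]
  up <- pairs$gene_id[abs(pairs$rna_log2fc) < 1 & pairs$protein_log2fc > 0.32]
  expect_setequal(out$gene_id[out$group == "translation_down"], down)
  expect_setequal(out$gene_id[out$group == "translation_up"], up)
})

test_that("signature derivation is the intersection and is monotone", {
  pairs <- classify_translation_groups(data.frame(
    gene_id = paste0("g", 1:6),
    protein_log2fc = c(-1, -1, -1, 1, 0, 0),
    rna_log2fc = c(0, 0, 0, 0, 0, 2)
  ))
  sig <- derive_signature(pairs, c("g1", "g2", "g5"))
  expect_equal(sig$genes, c("g1", "g2")) # 3 down, 2 of them members
  full <- derive_signature(pairs, paste0("g", 1:6))
  expect_equal(full$genes, c("g1", "g2", "g3")) # members = universe
  expect_true(all(sig$genes %in% full$genes)) # monotone in the member set
  expect_warning(empty <- derive_signature(pairs, "g6"), "empty")
  expect_length(empty$genes, 0)
})

test_that("superposition test matches the 2x2 closed form", {
  calls <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      log2fc = rep(c(-1, 1), 500),
                      significant = rep(c(TRUE, FALSE), 500))
  sig <- calls$gene_id[calls$significant][1:40]
  res <- superposition_test(sig, calls, "down")
  a <- res$contingency[1, 1]
  oracle <- chisq_2x2(a, res$contingency[1, 2],
                      res$contingency[2, 1], res$contingency[2, 2])
  expect_equal(res$chi2, oracle$chi2, tolerance = 1e-12)
  expect_lt(res$p, 1e-8) # signature drawn from the called set

  none <- superposition_test(character(0), calls, "down")
  expect_true(none$degenerate)
})

test_that("count filtering removes genes low in both groups only", {
  m <- rbind(
    A = c(12, 12, 12, 0, 0, 12),
    B = c(0, 0, 15, 3, 2, 20),
    C = c(50, 60, 70, 80, 90, 100)
  )
  colnames(m) <- paste0("s", 1:6)
  groups <- setNames(rep(c("g1", "g2"), each = 3), colnames(m))
  out <- filter_low_counts(m, groups)
  expect_setequal(rownames(out), c("A", "C")) # A: group1 fraction 0 -> kept
  all_high <- m[c("C"), , drop = FALSE]
  expect_identical(filter_low_counts(all_high, groups), all_high)
})

test_that("log-CPM follows the moderated transform", {
  m <- matrix(c(0, 1e6 - 0), ncol = 1,
              dimnames = list(c("zero", "rest"), "s1"))
  out <- log_cpm(m)
  expect_equal(out["zero", 1], -1.0, tolerance = 1e-3)

  # scale invariance up to the pseudo-count: doubling a sample's counts
  counts <- matrix(rpois(200, 100) + 1, 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  doubled <- counts; doubled[, 1] <- 2 * counts[, 1]
  d <- log_cpm(doubled)[, 1] - log_cpm(counts)[, 1]
  expect_lt(max(abs(d)), 0.02)

  # a count of k per million of library is about log2(k)
  lib <- matrix(c(8 * 1, 1e6 - 8), ncol = 1)
  expect_equal(log_cpm(lib)[1, 1], log2(8), tolerance = 0.1)
})

test_that("ssGSEA scores are rank-based and maximal for top placement", {
  set.seed(51)
  genes <- paste0("g", 1:100)
  sig <- genes[1:10]
  expr_top <- matrix(c(100:1), 100, 1, dimnames = list(genes, "top"))
  # signature genes hold the top 10 ranks in 'top'
  scores <- sapply(1:20, function(i) {
    perm <- matrix(sample(100), 100, 1, dimnames = list(genes, "p"))
    ssgsea_score(perm, sig, normalize = FALSE)$score
  })
  top_score <- ssgsea_score(expr_top, sig, normalize = FALSE)$score
  expect_true(all(top_score >= scores))

  # invariance under strictly monotone transforms of one sample
  e <- matrix(rnorm(200), 100, 2, dimnames = list(genes, c("a", "b")))
  s1 <- ssgsea_score(e, sig)
  e2 <- e; e2[, 1] <- exp(e[, 1])
  s2 <- ssgsea_score(e2, sig)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  const <- matrix(1, 100, 2, dimnames = list(genes, c("a", "b")))
  sc <- ssgsea_score(const, sig)
  expect_true(all(sc$flagged))
  expect_true(all(sc$score == 0))
  expect_error(ssgsea_score(e, "absent"), "no signature gene")
})

test_that("planted signature-high samples rank above null samples", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_expression_matrix(200, 30, signature = sprintf("g%04d", 1:25),
                                      n_high = 5, shift = 1, seed = 600 + s)
    sc <- ssgsea_score(log_cpm(sim$counts), sprintf("g%04d", 1:25))
    high <- sc$sample_id %in% sim$high_samples
    min(sc$score[high]) > max(sc$score[!high])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("extreme groups have round-half-up size and partition the samples", {
  mk <- function(n) data.frame(sample_id = sprintf("s%03d", 1:n),
                               score = seq_len(n) / n)
  g233 <- group_extremes(mk(233), 0.15)
  expect_equal(as.vector(table(g233$group)[c("high", "low")]), c(35L, 35L))
  g20 <- group_extremes(mk(20), 0.15)
  expect_equal(sum(g20$group == "high"), 3)
  g10 <- group_extremes(mk(10), 0.5) # 2k = N: empty middle allowed
  expect_equal(sum(g10$group == "middle"), 0)
  expect_error(group_extremes(mk(9), 0.5), "overlap")
  expect_length(intersect(which(g233$group == "high"),
                          which(g233$group == "low")), 0)
})

test_that("relative fragmentation matches the normalisation formula", {
  expect_identical(relative_fragmentation(37, 37), 1)
  expect_equal(relative_fragmentation(45, 20), 32.25)
  expect_lt(relative_fragmentation(20, 45), 1) # re-sensitisation direction
  expect_error(relative_fragmentation(45, 100), "\\[0, 100\\)")
})
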