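# Small shared statistics: the 2x2 Pearson chi-squared used by the
# enrichment and superposition tests, the pooled two-sample t-test used for
# tRNA and stratified fold-change comparisons, and the rank-based
# top-fraction membership rule shared by the background builder and the
# fold-change stratifier.

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Classical Pearson statistic without continuity correction,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with 1 degree of freedom.
#' Degenerate margins (a zero row or column total) give a statistic of 0 and
#' p = 1, flagged as degenerate. All arguments are vectorised.
#'
#' @param a,b,c,d Cell counts; rows are the two groups, columns the two
#'   outcomes, so the table is `rbind(c(a, b), c(c, d))`.
#' @return A data.frame with columns `chi2`, `p`, `min_expected` (smallest
#'   expected cell count) and `degenerate`.
#' @export
#' @examples
#' chisq_2x2(12, 8, 238, 742) # chi2 = 13.33
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
  min_expected <- ifelse(
    n > 0,
    pmin((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n,
    0
  )
  data.frame(
    chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    min_expected = min_expected,
    degenerate = den == 0
  )
}

#' Two-sample t-test robust to constant inputs
#'
#' Two-sided unpaired t-test (pooled variance by default, Welch optional).
#' The degenerate all-constant cases that make [stats::t.test()] error are
#' resolved explicitly: zero variance in both groups with equal means gives
#' p = 1; with unequal means the difference is unambiguous at this noise
#' model, so p is set to 0 and the result flagged.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `t`, `df`, `p` and `flagged` (degenerate variance).
#' @export
#' @examples
#' safe_t_test(c(4, 5, 6), c(1, 2, 3)) # t = 3.674, p = 0.0213
safe_t_test <- function(x, y, var_equal = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) {
    stop("t-test requires at least 2 observations per group")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1, flagged = FALSE))
    }
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0, flagged = TRUE))
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, flagged = FALSE)
}

#' Rank-based top-fraction membership
#'
#' Returns the ids of the `ceiling(frac * N)` items with the highest value.
#' Ties that span the cut are resolved deterministically by id (ascending),
#' so the member count is exact for every input.
#'
#' @param values Numeric vector.
#' @param ids Character vector of the same length; used for tie-breaking and
#'   as the return value.
#' @param frac Fraction in (0, 1]; default 0.25, the top-quartile rule.
#' @param decreasing Take the highest values if `TRUE` (default), the lowest
#'   otherwise.
#' @return Character vector of member ids, length `ceiling(frac * N)`.
#' @export
top_fraction <- function(values, ids, frac = 0.25, decreasing = TRUE) {
  stopifnot(length(values) == length(ids), frac > 0, frac <= 1)
  k <- ceiling(frac * length(values))
  ord <- if (decreasing) order(-values, ids) else order(values, ids)
  ids[ord[seq_len(k)]]
}
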