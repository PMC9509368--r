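## Shared statistical kernels used by every downstream stage.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value under the conditional hypergeometric
#' distribution, summing the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (the probability-mass rule used by [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer counts: group-1 present, group-1
#'   absent, group-2 present, group-2 absent.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisherExact2x2(10, 0, 0, 10)   # 2 / choose(20, 10)
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(counts == 0))
    stop("all-zero table: test undefined")
  ## degenerate margins: only one table possible
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(1)
  stats::fisher.test(matrix(counts, 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for sorted p-values, q_(i) = min over j >= i of
#' m p_(j) / j, capped at 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed, propagated).
#' @return Adjusted p-values (q-values), same length and order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sample t-test (pooled-variance by default, Welch optional)
#'
#' @param a,b Numeric vectors, each of length >= 2 with finite values.
#' @param welch Use the Welch (unequal-variance) statistic instead of the
#'   pooled-variance Student statistic.
#' @return List with `statistic` (t), `df`, and two-tailed `p_value`.
#'   Two groups with zero variance and equal means return t = 0, p = 1.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2, p_value = 1))
    ## degenerate: infinite t, p -> 0
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson correlation with simple-regression F-test p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; each must be
#'   non-constant.
#' @return List with `r`, `r_squared` and `p_value` (F test of the simple
#'   linear regression, equivalent to the two-sided correlation test).
#' @export
pearsonLinear <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least three points")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  n <- length(x)
  r2 <- r * r
  ## F statistic of the one-predictor regression: F = r^2 (n-2) / (1-r^2)
  p <- if (r2 >= 1) 0 else stats::pf(r2 * (n - 2) / (1 - r2), 1, n - 2,
                                     lower.tail = FALSE)
  list(r = r, r_squared = r2, p_value = p)
}

#' Fold change between two frequencies
#'
#' Ratio of the larger to the smaller frequency. A single zero frequency
#' yields `Inf` (a fixed difference passes any finite threshold); two zero
#' frequencies yield 1 (no change).
#'
#' @param freq_a,freq_b Frequencies in \[0, 1\] (vectorised).
#' @return Fold change >= 1, possibly `Inf`.
#' @export
foldChange <- function(freq_a, freq_b) {
  if (any(freq_a < 0 | freq_a > 1 | freq_b < 0 | freq_b > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  hi <- pmax(freq_a, freq_b)
  lo <- pmin(freq_a, freq_b)
  fc <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  fc
}

#' Silk fineness in dtex
#'
#' F(dtex) = 10000 x silk weight (g) / silk length (m): the linear mass
#' density of a reeled fibre, grams per 10,000 metres.
#'
#' @param weight_g Silk weight in grams (>= 0).
#' @param length_m Silk length in metres (> 0).
#' @return Fineness in dtex.
#' @examples
#' silkFineness(0.25, 1250)  # 2 dtex
#' @export
silkFineness <- function(weight_g, length_m) {
  if (any(length_m <= 0)) stop("silk length must be positive")
  if (any(weight_g < 0)) stop("silk weight must be non-negative")
  10000 * weight_g / length_m
}

## Shared presence/absence frequency-differentiation engine: one 2x2
## Fisher test per feature, BH across all features, carrier/presence
## fold change.  Used by both the orthogroup scan and the SV scan.
.freqDifferentiation <- function(present_a, n_a, present_b, n_b,
                                 fdr = 1e-4, fc = 2) {
  stopifnot(length(present_a) == length(present_b))
  if (n_a < 2 || n_b < 2) stop("each group needs at least two members")
  m <- length(present_a)
  p <- vapply(seq_len(m), function(i) {
    fisherExact2x2(present_a[i], n_a - present_a[i],
                   present_b[i], n_b - present_b[i])
  }, numeric(1))
  q <- bhAdjust(p)
  fa <- present_a / n_a
  fb <- present_b / n_b
  fcv <- foldChange(fa, fb)
  data.frame(
    freq_a = fa, freq_b = fb, p_value = p, q_value = q,
    fold_change = fcv,
    significant = q < fdr & fcv > fc,
    direction = ifelse(fb > fa, "increased",
                       ifelse(fb < fa, "reduced", "unchanged")),
    stringsAsFactors = FALSE)
}
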